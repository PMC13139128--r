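test_that("exact Shapley recovers the closed form for a linear model", {
  w <- c(1, -2, 0.5, 0, 3)
  f <- function(X) as.numeric(X %*% w) + 10
  set.seed(1)
  Xe <- matrix(rnorm(4 * 5), 4)
  base <- c(0.2, -0.1, 0, 1, 0.5)
  ex <- shapley_exact(f, Xe, base)
  expected <- sweep(Xe, 2, base) %*% diag(w)
  expect_lt(max(abs(ex$phi - expected)), 1e-9)
  # dummy axiom: weight-zero feature gets phi identically 0
  expect_true(all(ex$phi[, 4] == 0))
  # efficiency axiom
  expect_lt(max(abs(rowSums(ex$phi) - (ex$prediction - ex$baseline_value))), 1e-6)
})

test_that("symmetric duplicated features receive equal attribution", {
  f <- function(X) (X[, 1] + X[, 2])^2 + X[, 3]
  Xe <- matrix(c(1.2, 1.2, -0.5), 1)
  ex <- shapley_exact(f, Xe, baseline = c(0, 0, 0))
  expect_equal(ex$phi[1, 1], ex$phi[1, 2], tolerance = 1e-12)
})

test_that("exact Shapley matches the factorial-orderings oracle on a fitted tree", {
  set.seed(2)
  n <- 80
  X <- matrix(rnorm(n * 6), n)
  colnames(X) <- paste0("f", 1:6)
  y <- ifelse(X[, 1] > 0, 1.5, -0.5) + X[, 3] * X[, 5] + rnorm(n, 0, 0.1)
  tree <- rpart::rpart(y ~ ., data = data.frame(X, y = y),
                       control = rpart::rpart.control(maxdepth = 4))
  f <- function(M) {
    colnames(M) <- paste0("f", 1:6)
    unname(predict(tree, as.data.frame(M)))
  }
  base <- colMeans(X)
  ex <- shapley_exact(f, X[1:3, , drop = FALSE], base)
  for (s in 1:3) {
    oracle <- shapley_orderings_oracle(f, X[s, ], base)
    expect_lt(max(abs(ex$phi[s, ] - oracle)), 1e-9)
  }
})

test_that("exact enumeration refuses p > 16 and points to the sampler", {
  f <- function(X) rowSums(X)
  expect_error(shapley_exact(f, matrix(0, 1, 17), rep(0, 17)), "shapley_sampled")
})

test_that("sampled Shapley agrees with exact within Monte-Carlo error", {
  set.seed(3)
  X <- matrix(rnorm(60 * 6), 60)
  y <- X[, 1]^2 - X[, 2] + 0.5 * X[, 4] * X[, 1] + rnorm(60, 0.05)
  fit <- rf_fit(X, y, n_trees = 50, seed = 4)
  base <- colMeans(X)
  Xe <- X[1:4, , drop = FALSE]
  ex <- shapley_exact(fit, Xe, base)
  sm <- shapley_sampled(fit, Xe, base, n_permutations = 256, seed = 5)
  within3 <- abs(sm$phi - ex$phi) <= 3 * pmax(sm$se, 1e-12)
  expect_gte(mean(within3), 0.95)
  # deterministic given seed
  sm2 <- shapley_sampled(fit, Xe, base, n_permutations = 256, seed = 5)
  expect_identical(sm$phi, sm2$phi)
})

test_that("doubling permutations does not worsen the Monte-Carlo error", {
  # interactions make per-permutation contributions vary, so the estimator
  # has genuine Monte-Carlo error (a linear model would be exact at any B)
  f <- function(X) X[, 1] * X[, 2] + X[, 3]^2 - X[, 4] * X[, 5] + X[, 2]
  set.seed(6)
  Xe <- matrix(rnorm(3 * 5), 3)
  base <- rep(0.3, 5)
  exact <- shapley_exact(f, Xe, base)$phi
  err <- function(B) {
    mean(vapply(1:5, function(s) {
      sm <- shapley_sampled(f, Xe, base, n_permutations = B, seed = s)
      mean(abs(sm$phi - exact))
    }, numeric(1)))
  }
  expect_lte(err(128), err(32))
})

test_that("a constant model attributes nothing", {
  f <- function(X) rep(2.5, nrow(X))
  sm <- shapley_sampled(f, matrix(rnorm(10), 2), rep(0, 5),
                        n_permutations = 16, seed = 7)
  expect_true(all(sm$phi == 0))
  ex <- shapley_exact(f, matrix(rnorm(10), 2), rep(0, 5))
  expect_true(all(ex$phi == 0))
})

test_that("ranking orders by mean absolute phi with deterministic ties", {
  expl <- structure(list(
    phi = cbind(c(0.1, -0.1), c(1, 1), c(0, 0)),
    values = matrix(rnorm(6), 2), baseline_value = 0,
    prediction = c(1, 1), method = "exact"), class = "shap_explanation")
  rk <- shap_ranking(expl, wavelengths = c(500, 700, 900))
  expect_equal(rk$wavelength, c(700, 500, 900))

  zero <- expl
  zero$phi <- matrix(0, 2, 3)
  rk0 <- shap_ranking(zero, wavelengths = c(500, 700, 900))
  expect_equal(rk0$feature, 1:3) # stable order under all-zero attribution
})

test_that("the dominant generator band ranks first and exports are well-formed", {
  set.seed(8)
  n <- 120
  X <- matrix(rnorm(n * 8), n)
  y <- 2 * X[, 5] + 0.1 * X[, 2] + rnorm(n, 0, 0.1)
  fit <- rf_fit(X, y, seed = 9)
  ex <- shapley_exact(fit, X[1:20, ], colMeans(X))
  rk <- shap_ranking(ex, wavelengths = seq(2000, 2350, by = 50))
  expect_equal(rk$feature[1], 5)
  lg <- shap_long(ex, wavelengths = seq(2000, 2350, by = 50))
  expect_equal(nrow(lg), 20 * 8)
  expect_named(lg, c("sample", "feature", "wavelength", "value", "phi"))
})

test_that("band attribution signs follow the absorption mechanism", {
  # on raw reflectance, higher reflectance at pigment/protein bands means
  # shallower absorption and less nitrogen (negative value-phi association);
  # structural-carbohydrate absorption falls with nitrogen, flipping the sign
  ds <- simulate_dataset("NSS", seed = 55)
  idx <- wavelength_index(ds$spectra,
                          c(680, 970, 1450, 1940, 2045, 2180, 2340, 2385))
  X <- ds$spectra$reflectance[, idx]
  fit <- rf_fit(X, ds$nitrogen, seed = 10,
                wavelengths = ds$spectra$wavelengths[idx])
  ex <- shapley_exact(fit, X[1:60, ], colMeans(X))
  rk <- shap_ranking(ex, wavelengths = ds$spectra$wavelengths[idx])
  assoc <- setNames(rk$value_phi_cor, rk$wavelength)
  expect_true(all(assoc[c("680", "2045", "2180")] < 0))
  expect_true(all(assoc[c("2340", "2385")] > 0))
  # the strong protein bands dominate the ranking
  expect_true(all(c(2045, 2180) %in% rk$wavelength[1:3]))
})
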