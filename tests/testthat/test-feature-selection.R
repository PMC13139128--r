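test_that("PLS1 fits an exact single-latent problem with one component", {
  set.seed(1)
  t_sc <- rnorm(30)
  X <- t_sc %o% rnorm(8)
  y <- 2 * t_sc + 1
  fit <- pls1_fit(X, y, 1)
  expect_lt(sqrt(mean((predict(fit, X) - y)^2)), 1e-6)
})

test_that("first PLS weight is proportional to X'y for orthonormal columns", {
  set.seed(2)
  Q <- qr.Q(qr(matrix(rnorm(40 * 6), 40)))
  y <- rnorm(40)
  fit <- pls1_fit(Q, y, 3)
  # centring shifts X'y slightly; compare on the centred data the fit uses
  Qc <- sweep(Q, 2, colMeans(Q))
  yc <- y - mean(y)
  w_expect <- crossprod(Qc, yc)
  w_expect <- w_expect / sqrt(sum(w_expect^2))
  expect_lt(max(abs(abs(fit$W[, 1]) - abs(w_expect))), 1e-10)
})

test_that("permuted response yields null-level RMSECV at every component count", {
  set.seed(3)
  X <- matrix(rnorm(50 * 30), 50)
  y <- X[, 1] + rnorm(50, 0, 0.1)
  y_perm <- sample(y)
  cv <- pls_rmsecv(X, y_perm, max_components = 8, folds = 5, seed = 9)
  expect_true(all(cv$rmsecv >= sd(y_perm) * 0.8))
  # and the true signal is recoverable for contrast
  cv_true <- pls_rmsecv(X, y, max_components = 8, folds = 5, seed = 9)
  expect_lt(min(cv_true$rmsecv), sd(y) * 0.5)
})

test_that("CARS EDF endpoints force full retention at run 1 and two variables at run N", {
  r <- cars_edf_ratios(2101, 50)
  expect_equal(ceiling(r[1] * 2101), 2101)
  expect_equal(r[50] * 2101, 2, tolerance = 1e-9)
  expect_true(all(diff(r) < 0))
})

test_that("CARS traces are reproducible, nested, and shrink monotonically", {
  pb <- planted_bands_data(n = 60, p = 120, centers = c(30, 60, 90), seed = 4)
  tr1 <- cars_select(pb$X, pb$y, n_runs = 30, seed = 77)
  tr2 <- cars_select(pb$X, pb$y, n_runs = 30, seed = 77)
  expect_identical(tr1$selected, tr2$selected)
  counts <- vapply(tr1$runs, `[[`, numeric(1), "n_retained")
  caps <- ceiling(cars_edf_ratios(120, 30) * 120)
  expect_true(all(counts <= caps[seq_along(counts)]))
  expect_true(all(vapply(tr1$runs, function(r)
    all(r$retained %in% seq_len(120)), logical(1))))
  expect_equal(tr1$rmsecv, min(vapply(tr1$runs, `[[`, numeric(1), "rmsecv")))
})

test_that("SPA chain equals descending-norm order for orthogonal columns", {
  Q <- qr.Q(qr(matrix(rnorm(30 * 5, 0, 1), 30))) %*% diag(c(5, 3, 9, 1, 7))
  norms <- sqrt(colSums(Q^2))
  ch <- spa_chain(Q, start = which.max(norms), max_len = 5)
  expect_equal(ch$chain, order(norms, decreasing = TRUE))
  expect_equal(ch$residual_norms, sort(norms, decreasing = TRUE),
               tolerance = 1e-10)
})

test_that("SPA never selects a duplicated column twice", {
  set.seed(6)
  X <- matrix(rnorm(25 * 6), 25)
  X <- cbind(X, X[, 3]) # exact duplicate of column 3
  for (s in seq_len(ncol(X))) {
    ch <- spa_chain(X, start = s, max_len = 7)
    expect_lte(sum(ch$chain %in% c(3, 7)), 1)
  }
})

test_that("SPA residual norms match an explicit Gram-Schmidt oracle", {
  set.seed(7)
  X <- matrix(rnorm(20 * 12), 20)
  ch <- spa_chain(X, start = 4, max_len = 12)
  expect_lt(max(abs(ch$residual_norms - gram_schmidt_norms(X, ch$chain))), 1e-8)
})

test_that("CARS-SPA composition is deterministic and contained in the CARS winner", {
  pb <- planted_bands_data(n = 60, p = 150, centers = c(40, 80, 120), seed = 5)
  sel1 <- cars_spa(pb$X, pb$y, max_vars = 10, n_runs = 25, seed = 42)
  sel2 <- cars_spa(pb$X, pb$y, max_vars = 10, n_runs = 25, seed = 42)
  expect_identical(sel1$indices, sel2$indices)
  expect_lte(length(sel1$indices), 10)
  expect_true(all(sel1$indices %in% sel1$cars$selected))
})

test_that("the shipped reference wavelength set loads with 15 bands", {
  ref <- reference_wavelengths()
  expect_length(ref$wavelengths, 15)
  expect_equal(ref$wavelengths[1], 411)
  expect_equal(ref$wavelengths[15], 2394)
  expect_equal(ref$n_cars, 102)
  expect_true(all(diff(ref$wavelengths) > 0))
})

test_that("SPA projection chains are less collinear than random subsets", {
  # collinearity minimisation lives in the projection chain (the RMSE stage
  # may then prefer a shorter, possibly correlated prefix); band-structured
  # noise gives correlated neighbours that random draws occasionally pair up
  vif_of <- function(X, cols) {
    Xs <- scale(X[, cols])
    R <- crossprod(Xs) / (nrow(Xs) - 1)
    median(diag(solve(R)))
  }
  wins <- 0
  for (s in 1:5) {
    set.seed(200 + s)
    raw <- matrix(rnorm(70 * 110), 70)
    X <- sapply(1:100, function(j) rowMeans(raw[, j:(j + 10)]))
    ch <- spa_chain(X, start = 10 * s, max_len = 6)
    vif_rand <- replicate(20, vif_of(X, sample(100, length(ch$chain))))
    wins <- wins + (vif_of(X, ch$chain) < median(vif_rand))
  }
  expect_gte(wins, 4)
})
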