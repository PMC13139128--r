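test_that("metrics match hand arithmetic and the two-pass oracle", {
  y <- c(2.0, 2.5, 3.0); p <- c(2.1, 2.4, 3.1)
  m <- compute_metrics(y, p)
  expect_equal(m$rmse, 0.1, tolerance = 1e-12)
  expect_equal(m$rpd_printed, 5.148, tolerance = 1e-3)
  expect_equal(m$rpd_conventional, sd(y) / 0.1, tolerance = 1e-12)

  set.seed(1)
  yt <- rnorm(40, 2.5, 0.2); yp <- yt + rnorm(40, 0, 0.1)
  m2 <- compute_metrics(yt, yp)
  # independent two-pass oracle
  sse <- 0; sst <- 0; yb <- sum(yt) / length(yt)
  for (i in seq_along(yt)) {
    sse <- sse + (yt[i] - yp[i])^2
    sst <- sst + (yt[i] - yb)^2
  }
  expect_equal(m2$r2, 1 - sse / sst, tolerance = 1e-12)
  expect_equal(m2$rmse, sqrt(sse / length(yt)), tolerance = 1e-12)

  # order invariance
  ord <- sample(40)
  m3 <- compute_metrics(yt[ord], yp[ord])
  expect_equal(m2$r2, m3$r2)
  expect_equal(m2$rmse, m3$rmse)
})

test_that("perfect and mean predictors hit the metric boundary cases", {
  y <- c(1, 2, 3, 4)
  perfect <- compute_metrics(y, y)
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$rmse, 0)
  null_model <- compute_metrics(y, rep(mean(y), 4))
  expect_equal(null_model$r2, 0)
  expect_equal(null_model$rpd_printed, 0)
  expect_error(compute_metrics(c(1, 1), c(1, 2)), "zero variance")
})

test_that("RPD variants coincide for near-perfect predictions", {
  set.seed(2)
  y <- rnorm(100, 2.5, 0.2)
  p <- y + rnorm(100, 0, 1e-6)
  m <- compute_metrics(y, p)
  expect_equal(m$rpd_printed, m$rpd_conventional, tolerance = 1e-3)
})

test_that("the within-one-sd fraction matches the normal expectation", {
  set.seed(3)
  d <- residual_diagnostics(rnorm(1e5), rep(0, 1e5))
  expect_equal(d$fraction_within_1sd, 0.683, tolerance = 0.005)
  expect_equal(sum(d$histogram$counts), 1e5)
})

test_that("alternating +/-c residuals are all inside the boundary-inclusive band", {
  r <- rep(c(0.2, -0.2), 10)
  d <- residual_diagnostics(r, rep(0, 20))
  expect_equal(d$fraction_within_1sd, 1.0)
})

test_that("Q-Q of exact Blom-position normal quantiles lies on the identity", {
  n <- 50
  r <- qnorm((seq_len(n) - 3 / 8) / (n + 1 / 4))
  d <- residual_diagnostics(r, rep(0, n))
  expect_lt(max(abs(d$qq$theoretical - d$qq$sample)), 1e-6)
})

test_that("cross-stage validation on the training data equals in-sample metrics", {
  set.seed(4)
  X <- matrix(rnorm(60 * 15), 60)
  y <- X[, 3] + rnorm(60, 0, 0.2)
  fit <- rf_fit(X, y, seed = 2, wavelengths = seq(500, 1900, by = 100))
  cv <- cross_stage_validate(fit, X, y)
  m <- compute_metrics(y, predict(fit, X))
  expect_equal(cv$metrics$r2, m$r2)
  expect_equal(cv$metrics$rmse, m$rmse)

  # wavelength mismatch is rejected with the missing band named
  ext <- spectra_set(matrix(runif(60 * 5), 60), seq(500, 900, by = 100))
  expect_error(cross_stage_validate(fit, ext, y), "missing model bands")
})

test_that("an exchangeable external set scores close to the internal test set", {
  cfg <- generator_config("NSS")
  ds <- simulate_dataset("NSS", seed = 31)
  prep <- preprocess(ds$spectra, "sg-sd")
  sp <- spxy_split(prep, ds$nitrogen, 0.6)
  idx <- sort(wavelength_index(prep, reference_wavelengths()$wavelengths))
  fit <- rf_fit(prep$reflectance[sp$train, idx], ds$nitrogen[sp$train],
                seed = 7, wavelengths = prep$wavelengths[idx])
  r2_test <- compute_metrics(ds$nitrogen[sp$test],
                             predict(fit, prep$reflectance[sp$test, idx]))$r2
  ds2 <- simulate_dataset("NSS", seed = 32)
  prep2 <- preprocess(ds2$spectra, "sg-sd")
  cv <- cross_stage_validate(fit, prep2, ds2$nitrogen)
  expect_lt(abs(cv$metrics$r2 - r2_test), 0.1)
  expect_true(is.finite(cv$slope))
})
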