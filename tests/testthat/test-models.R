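test_that("random forest honours its structural constraints", {
  set.seed(1)
  X <- matrix(rnorm(200 * 5), 200)
  y <- 2 * X[, 2] + rnorm(200, 0, 0.2)
  fit <- rf_fit(X[1:150, ], y[1:150], seed = 3)
  expect_equal(fit$hyperparameters,
               list(n_trees = 300, max_depth = 8, min_leaf = 3))
  m <- compute_metrics(y[151:200], predict(fit, X[151:200, ]))
  expect_gte(m$r2, 0.9)

  # no tree path exceeds 8 splits
  depth_of_tree <- function(info) {
    depth <- rep(0L, nrow(info))
    for (i in seq_len(nrow(info))[-1]) {
      parent <- which(info$leftChild == info$nodeID[i] |
                        info$rightChild == info$nodeID[i])
      depth[i] <- depth[parent] + 1L
    }
    max(depth)
  }
  depths <- vapply(1:20, function(t)
    depth_of_tree(ranger::treeInfo(fit$fit, t)), integer(1))
  expect_true(all(depths <= 8))

  # constant response reproduced exactly
  cfit <- rf_fit(X[1:50, ], rep(2.5, 50), seed = 1)
  expect_true(all(abs(predict(cfit, X[51:60, ]) - 2.5) < 1e-12))

  expect_error(rf_fit(X[1:5, ], y[1:5]), "at least 6 samples")
})

test_that("random forest is reproducible given the seed", {
  set.seed(2)
  X <- matrix(rnorm(80 * 6), 80)
  y <- X[, 1] - X[, 4] + rnorm(80, 0, 0.3)
  p1 <- predict(rf_fit(X, y, seed = 11), X)
  p2 <- predict(rf_fit(X, y, seed = 11), X)
  expect_identical(p1, p2)
})

test_that("the SVM grid spans the stated integer exponents", {
  expect_length(eval(formals(svm_fit)$C_grid), 15)
  expect_length(eval(formals(svm_fit)$gamma_grid), 17)
  expect_equal(range(eval(formals(svm_fit)$C_grid)), c(2^-5, 2^9))
  expect_equal(range(eval(formals(svm_fit)$gamma_grid)), c(2^-15, 2^1))
})

test_that("SVM learns a smooth nonlinearity and standardisation guards scaling", {
  set.seed(4)
  X <- matrix(runif(300 * 3, -2, 2), 300)
  y <- sin(2 * X[, 1]) + rnorm(300, 0, 0.05)
  tr <- 1:220; te <- 221:300
  fit <- svm_fit(X[tr, ], y[tr], seed = 5)
  expect_gte(compute_metrics(y[te], predict(fit, X[te, ]))$r2, 0.85)
  g <- fit$hyperparameters$gamma
  expect_gt(g, 2^-15); expect_lt(g, 2^1) # grid interior

  # multiplying a feature by 10 changes neither predictions nor grid point
  X10 <- X; X10[, 2] <- X10[, 2] * 10
  small_C <- 2^(0:3); small_g <- 2^(-3:0)
  f1 <- svm_fit(X[tr, ], y[tr], C_grid = small_C, gamma_grid = small_g, seed = 5)
  f2 <- svm_fit(X10[tr, ], y[tr], C_grid = small_C, gamma_grid = small_g, seed = 5)
  expect_equal(f1$hyperparameters[c("C", "gamma")],
               f2$hyperparameters[c("C", "gamma")])
  expect_equal(predict(f1, X[te, ]), predict(f2, X10[te, ]), tolerance = 1e-8)

  expect_error(svm_fit(X[1:20, ], rep(1, 20)), "degenerate")
})

test_that("the CNN memorises a small sample with regularisation off", {
  set.seed(6)
  X <- matrix(rnorm(5 * 15), 5)
  y <- rnorm(5)
  fit <- cnn_fit(X, y, cnn_config(dropout = 0, l2_lambda = 0,
                                  max_iterations = 2000, learning_rate = 0.01,
                                  early_stop_patience = 2000,
                                  lr_patience = 2000, batch_size = 5,
                                  val_fraction = 0, seed = 8))
  expect_lte(sqrt(mean((predict(fit, X) - y)^2)), 0.02)
})

test_that("CNN parameter count matches the closed-form layer arithmetic", {
  cfg <- cnn_config(seed = 9)
  # p = 15: conv1 8*(3*1)+8, conv2 8*(3*8)+8, fc 24*32+32, out 32+1
  expect_equal(cnn_param_count(15, cfg), 32 + 200 + 800 + 33)
  set.seed(10)
  fit <- cnn_fit(matrix(rnorm(20 * 15), 20), rnorm(20),
                 cnn_config(max_iterations = 5, seed = 9))
  expect_equal(fit$n_parameters, cnn_param_count(15, cfg))
})

test_that("CNN training converges and is reproducible under a fixed seed", {
  set.seed(11)
  n <- 60
  X <- matrix(rnorm(n * 15), n)
  y <- 0.8 * X[, 4] - 0.5 * X[, 9] + rnorm(n, 0, 0.15)
  cfg <- cnn_config(seed = 12)
  fit <- cnn_fit(X, y, cfg)
  h <- fit$history
  expect_lt(h$train_rmse[nrow(h)], h$train_rmse[10]) # convergent trace
  fit2 <- cnn_fit(X, y, cfg)
  expect_identical(predict(fit, X), predict(fit2, X))

  expect_error(cnn_fit(X[, 1:5], y, cfg), "at least 8 features")
  expect_error(cnn_config(kernel_size = 4), "odd")
  expect_error(cnn_config(dropout = 1), "dropout")
})

test_that("fit/predict never touches test responses", {
  set.seed(13)
  X <- matrix(rnorm(100 * 10), 100)
  y <- X[, 1] + rnorm(100, 0, 0.1)
  tr <- 1:70; te <- 71:100
  y_mangled <- y
  y_mangled[te] <- 999 # if any fit read test targets, predictions would move
  for (fitter in list(
    function(yy) rf_fit(X[tr, ], yy[tr], seed = 1),
    function(yy) svm_fit(X[tr, ], yy[tr], C_grid = 2^(0:2),
                         gamma_grid = 2^(-2:0), seed = 1),
    function(yy) cnn_fit(X[tr, ], yy[tr],
                         cnn_config(max_iterations = 30, seed = 1))
  )) {
    p1 <- predict(fitter(y), X[te, ])
    p2 <- predict(fitter(y_mangled), X[te, ])
    expect_identical(p1, p2)
  }
})
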