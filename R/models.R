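new_model_bundle <- function(kind, fit, hyperparameters, wavelengths = NULL,
                             seed = NULL, ...) {
  structure(
    c(list(kind = kind, fit = fit, hyperparameters = hyperparameters,
           wavelengths = wavelengths, seed = seed), list(...)),
    class = "model_bundle"
  )
}

#' @export
print.model_bundle <- function(x, ...) {
  cat(sprintf("<model_bundle> %s over %d feature(s)%s\n", x$kind, x$n_features,
              if (!is.null(x$wavelengths))
                paste0(" (", paste(round(x$wavelengths), collapse = ", "), " nm)")
              else ""))
  invisible(x)
}

#' Predict from a fitted model bundle
#'
#' @param object a `model_bundle` from [rf_fit()], [svm_fit()], [cnn_fit()],
#'   or [pso_cnn_fit()].
#' @param newdata numeric matrix with the model's feature columns.
#' @param ... ignored.
#' @return Numeric vector of predictions (nitrogen %).
#' @export
predict.model_bundle <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features)
    stop("model expects ", object$n_features, " features, got ", ncol(newdata))
  switch(object$kind,
    rf = {
      colnames(newdata) <- object$feature_names
      predict(object$fit, data = as.data.frame(newdata),
              num.threads = 1)$predictions
    },
    svm = {
      Z <- sweep(sweep(newdata, 2, object$x_center), 2, object$x_scale, "/")
      colnames(Z) <- object$feature_names
      as.numeric(predict(object$fit, Z))
    },
    cnn = ,
    pso_cnn = {
      Z <- sweep(sweep(newdata, 2, object$x_center), 2, object$x_scale, "/")
      cfg <- object$hyperparameters
      z <- .cnn_predict_cpp(object$fit, Z, cfg$kernel_size,
                            cfg$kernels_per_layer, cfg$fc_width)
      as.numeric(z) * object$y_scale + object$y_center
    },
    stop("unknown model kind: ", object$kind)
  )
}

#' Random-forest regression on selected wavelengths
#'
#' Seeded random forest with the fixed structural constraints used throughout
#' the pipeline: 300 trees, maximal depth 8, at least 3 samples per leaf.
#'
#' @param X numeric matrix of selected-wavelength features (n x p).
#' @param y numeric response (nitrogen %).
#' @param n_trees,max_depth,min_leaf forest constraints.
#' @param seed integer seed.
#' @param wavelengths optional nm labels of the feature columns, stored for
#'   cross-stage prediction and attribution.
#' @return A `model_bundle` of kind `"rf"`.
#' @export
rf_fit <- function(X, y, n_trees = 300, max_depth = 8, min_leaf = 3,
                   seed = 1L, wavelengths = NULL) {
  X <- as.matrix(X)
  if (nrow(X) < 2 * min_leaf)
    stop("need at least ", 2 * min_leaf, " samples (2 * min_leaf)")
  feature_names <- sprintf("f%03d", seq_len(ncol(X)))
  colnames(X) <- feature_names
  df <- as.data.frame(X)
  df$.y <- y
  fit <- ranger::ranger(
    dependent.variable.name = ".y", data = df,
    num.trees = n_trees, max.depth = max_depth, min.bucket = min_leaf,
    seed = seed, num.threads = 1
  )
  new_model_bundle("rf", fit,
                   list(n_trees = n_trees, max_depth = max_depth,
                        min_leaf = min_leaf),
                   wavelengths = wavelengths, seed = seed,
                   n_features = ncol(X), feature_names = feature_names)
}

#' RBF support-vector regression with seeded grid search
#'
#' Epsilon-SVR with a radial basis kernel. Features are standardised with
#' training statistics (so per-column rescaling of the input cannot change the
#' model), and `(C, gamma)` are chosen by seeded k-fold cross-validated RMSE
#' over the integer-exponent grids `C = 2^(-5..9)`, `gamma = 2^(-15..1)`.
#'
#' @param X numeric matrix of selected-wavelength features.
#' @param y numeric response.
#' @param C_grid,gamma_grid hyperparameter grids.
#' @param folds CV folds (default 5).
#' @param epsilon epsilon-tube width (default 0.01).
#' @param seed integer seed (fold assignment).
#' @param wavelengths optional nm labels.
#' @return A `model_bundle` of kind `"svm"` carrying the chosen `C`, `gamma`
#'   and the CV RMSE grid.
#' @export
svm_fit <- function(X, y, C_grid = 2^(-5:9), gamma_grid = 2^(-15:1),
                    folds = 5, epsilon = 0.01, seed = 1L, wavelengths = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (var(y) == 0) stop("degenerate response: var(y) = 0")
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl == 0] <- 1
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  feature_names <- sprintf("f%03d", seq_len(ncol(Z)))
  colnames(Z) <- feature_names

  fold_id <- with_seed(seed, sample(rep(seq_len(folds), length.out = n)))
  cv_rmse <- matrix(NA_real_, length(C_grid), length(gamma_grid),
                    dimnames = list(paste0("C=", C_grid),
                                    paste0("g=", gamma_grid)))
  for (ci in seq_along(C_grid)) {
    for (gi in seq_along(gamma_grid)) {
      pred <- numeric(n)
      for (k in seq_len(folds)) {
        hold <- fold_id == k
        fit <- e1071::svm(Z[!hold, , drop = FALSE], y[!hold],
                          type = "eps-regression", kernel = "radial",
                          cost = C_grid[ci], gamma = gamma_grid[gi],
                          epsilon = epsilon, scale = FALSE)
        pred[hold] <- predict(fit, Z[hold, , drop = FALSE])
      }
      cv_rmse[ci, gi] <- sqrt(mean((y - pred)^2))
    }
  }
  best <- arrayInd(which.min(cv_rmse), dim(cv_rmse))
  C <- C_grid[best[1]]; gamma <- gamma_grid[best[2]]
  fit <- e1071::svm(Z, y, type = "eps-regression", kernel = "radial",
                    cost = C, gamma = gamma, epsilon = epsilon, scale = FALSE)
  new_model_bundle("svm", fit,
                   list(C = C, gamma = gamma, epsilon = epsilon),
                   wavelengths = wavelengths, seed = seed,
                   n_features = ncol(X), feature_names = feature_names,
                   x_center = ctr, x_scale = scl, cv_rmse = cv_rmse)
}
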