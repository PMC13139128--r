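#' Configuration of the 1D convolutional network
#'
#' Architecture and training settings of the compact spectral CNN:
#' Conv(8 kernels, size 3, same padding) -> ReLU -> MaxPool(2, stride 2) ->
#' Conv(8, 3, same) -> ReLU -> MaxPool(2, 2) -> Dropout(0.5) -> Flatten ->
#' FC(`fc_width`) -> ReLU -> Linear(1); mean-squared-error loss plus an L2
#' penalty `l2_lambda * sum(weights^2)`; Adam optimiser with the learning rate
#' multiplied by `lr_decay_factor` when the monitored loss plateaus for
#' `lr_patience` epochs; early stopping on an internal validation fold.
#'
#' @param kernels_per_layer convolution kernels per layer (default 8).
#' @param kernel_size kernel length, odd (default 3).
#' @param fc_width fully connected layer width (default 32).
#' @param dropout dropout rate before the fully connected layer, in `[0, 1)`.
#' @param l2_lambda L2 penalty coefficient (default 0.001).
#' @param batch_size minibatch size (default 32; capped at the training size).
#' @param learning_rate initial Adam learning rate (default 0.001).
#' @param lr_decay_factor plateau decay multiplier (default 0.1).
#' @param lr_patience epochs without improvement before decaying (default 40).
#' @param max_iterations maximal training epochs (default 500).
#' @param early_stop_patience epochs without improvement before stopping
#'   (default 150).
#' @param val_fraction fraction of the training rows held out internally for
#'   the monitored loss (default 0.2; 0 disables and monitors training loss).
#' @param min_delta minimal improvement counted as progress.
#' @param seed integer seed (weight init, shuffling, dropout).
#' @return An object of class `cnn_config`.
#' @export
cnn_config <- function(kernels_per_layer = 8, kernel_size = 3, fc_width = 32,
                       dropout = 0.5, l2_lambda = 0.001, batch_size = 32,
                       learning_rate = 0.001, lr_decay_factor = 0.1,
                       lr_patience = 40, max_iterations = 500,
                       early_stop_patience = 150, val_fraction = 0.2,
                       min_delta = 1e-5, seed = 1L) {
  if (kernel_size %% 2 != 1) stop("kernel_size must be odd")
  if (batch_size < 1) stop("batch_size must be >= 1")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (lr_decay_factor <= 0 || lr_decay_factor > 1)
    stop("lr_decay_factor must be in (0, 1]")
  if (l2_lambda < 0) stop("l2_lambda must be >= 0")
  structure(as.list(environment()), class = "cnn_config")
}

#' Parameter count of the spectral CNN
#'
#' Closed-form count of trainable parameters for an input of length `p`:
#' two convolutions, the fully connected layer on the flattened
#' `floor(floor(p/2)/2) * kernels` features, and the linear output.
#'
#' @param p input length (number of selected wavelengths).
#' @param config a [cnn_config()].
#' @return Integer parameter count.
#' @export
cnn_param_count <- function(p, config = cnn_config()) {
  k <- config$kernels_per_layer; ks <- config$kernel_size
  fcw <- config$fc_width
  flat <- (p %/% 2 %/% 2) * k
  (ks * 1 * k + k) + (ks * k * k + k) + (flat * fcw + fcw) + (fcw + 1)
}

#' Fit the 1D convolutional network
#'
#' Standardises features and response with training statistics, holds out an
#' internal validation fold (seeded) for plateau detection and early stopping,
#' trains with Adam, and restores the best-validation weights. The recorded
#' loss history (training and validation RMSE per epoch, in original response
#' units) is kept on the returned bundle.
#'
#' @param X numeric matrix of selected-wavelength features (n x p, p >= 8).
#' @param y numeric response (nitrogen %).
#' @param config a [cnn_config()].
#' @param validation optional list `(X, y)` used as the monitored fold instead
#'   of the internal split.
#' @param wavelengths optional nm labels.
#' @return A `model_bundle` of kind `"cnn"` with `history` (train/val RMSE per
#'   epoch), `best_epoch`, and the standardisation vectors.
#' @export
cnn_fit <- function(X, y, config = cnn_config(), validation = NULL,
                    wavelengths = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (p < 8) stop("need at least 8 features for two pooling layers, got ", p)
  if (n < 3) stop("need at least 3 training samples")
  ctr <- colMeans(X); scl <- apply(X, 2, sd); scl[scl == 0] <- 1
  y_ctr <- mean(y); y_scl <- sd(y); if (y_scl == 0) y_scl <- 1
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  yz <- (y - y_ctr) / y_scl

  with_seed(config$seed, {
    if (!is.null(validation)) {
      Zfit <- Z; yfit <- yz
      Zval <- sweep(sweep(as.matrix(validation$X), 2, ctr), 2, scl, "/")
      yval <- (validation$y - y_ctr) / y_scl
    } else if (config$val_fraction > 0 && n >= 10) {
      n_val <- max(2, round(config$val_fraction * n))
      hold <- sample(n, n_val)
      Zfit <- Z[-hold, , drop = FALSE]; yfit <- yz[-hold]
      Zval <- Z[hold, , drop = FALSE]; yval <- yz[hold]
    } else {
      Zfit <- Z; yfit <- yz
      Zval <- matrix(0, 0, p); yval <- numeric(0)
    }
    res <- .cnn_train_cpp(Zfit, yfit, Zval, yval, unclass(config))
    history <- data.frame(
      epoch = seq_along(res$train_history),
      train_rmse = res$train_history * y_scl,
      val_rmse = if (length(res$val_history)) res$val_history * y_scl else NA_real_
    )
    new_model_bundle("cnn", res$weights, config,
                     wavelengths = wavelengths, seed = config$seed,
                     n_features = p, x_center = ctr, x_scale = scl,
                     y_center = y_ctr, y_scale = y_scl,
                     history = history, best_epoch = res$best_epoch,
                     epochs_run = res$epochs_run,
                     val_rmse = res$best_monitor * y_scl,
                     n_parameters = sum(lengths(lapply(res$weights, as.numeric))))
  })
}
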