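#' Regression metrics: R2, RMSE, and two RPD variants
#'
#' * `r2 = 1 - sum((y - yhat)^2) / sum((y - ybar)^2)`
#' * `rmse = sqrt(sum((y - yhat)^2) / n)`
#' * `rpd_printed = sqrt(sum((yhat - ybar)^2) / (n - 1)) / rmse` - the
#'   relative-percent-difference form with predicted deviations in the
#'   numerator, exactly as commonly printed in the application literature.
#' * `rpd_conventional = sd(y) / rmse` - the usual chemometric ratio of the
#'   reference-value standard deviation (n - 1 denominator) to the RMSE.
#'
#' The two RPD forms coincide when predictions are perfect. RPD below 1.4 is
#' read as poor, 1.4-2.0 moderate, above 2.0 strong.
#'
#' @param y_true observed values (nitrogen %).
#' @param y_pred predicted values, same length.
#' @return An object of class `regression_metrics`: list with `r2`, `rmse`,
#'   `rpd_printed`, `rpd_conventional`, `n`.
#' @export
compute_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (length(y_true) < 2) stop("need at least 2 samples")
  if (any(!is.finite(y_true)) || any(!is.finite(y_pred)))
    stop("non-finite values in predictions or observations")
  n <- length(y_true)
  ybar <- mean(y_true)
  sst <- sum((y_true - ybar)^2)
  if (sst == 0) stop("zero variance in y_true: R2 undefined")
  sse <- sum((y_true - y_pred)^2)
  rmse <- sqrt(sse / n)
  rpd_printed <- if (rmse == 0) Inf else
    sqrt(sum((y_pred - ybar)^2) / (n - 1)) / rmse
  rpd_conv <- if (rmse == 0) Inf else sd(y_true) / rmse
  structure(list(r2 = 1 - sse / sst, rmse = rmse,
                 rpd_printed = rpd_printed, rpd_conventional = rpd_conv,
                 n = n),
            class = "regression_metrics")
}

#' @export
print.regression_metrics <- function(x, ...) {
  cat(sprintf("R2 = %.3f, RMSE = %.3f, RPD = %.3f (printed form %.3f), n = %d\n",
              x$r2, x$rmse, x$rpd_conventional, x$rpd_printed, x$n))
  invisible(x)
}

#' Residual diagnostics
#'
#' Residuals (observed minus predicted), the fraction falling within one standard
#' deviation of their mean (boundary inclusive, n - 1 sd), a 20-bin histogram
#' with fitted-normal curve ordinates, and Q-Q pairs of the sorted residuals
#' against standard-normal quantiles at Blom plotting positions
#' `(i - 3/8) / (n + 1/4)`.
#'
#' @param y_true observed values.
#' @param y_pred predicted values.
#' @param bins histogram bin count (default 20).
#' @return An object of class `residual_diagnostics`: `residuals`,
#'   `fraction_within_1sd`, `sd_bounds`, `histogram` (breaks, counts, normal
#'   curve ordinates at bin midpoints), and `qq` (theoretical, sample).
#' @export
residual_diagnostics <- function(y_true, y_pred, bins = 20) {
  r <- y_true - y_pred
  n <- length(r)
  if (n < 10) stop("need at least 10 residuals")
  m <- mean(r); s <- sd(r)
  frac <- mean(abs(r - m) <= s)
  breaks <- seq(min(r), max(r), length.out = bins + 1)
  counts <- as.integer(table(cut(r, breaks, include.lowest = TRUE)))
  mids <- (breaks[-1] + breaks[-(bins + 1)]) / 2
  curve <- dnorm(mids, m, s) * n * diff(breaks)[1]
  pp <- (seq_len(n) - 3 / 8) / (n + 1 / 4)
  structure(
    list(residuals = r, mean = m, sd = s,
         fraction_within_1sd = frac,
         sd_bounds = c(lower = m - s, upper = m + s),
         histogram = list(breaks = breaks, counts = counts,
                          midpoints = mids, normal_curve = curve),
         qq = data.frame(theoretical = qnorm(pp), sample = sort(r))),
    class = "residual_diagnostics"
  )
}

#' @export
print.residual_diagnostics <- function(x, ...) {
  cat(sprintf("<residual_diagnostics> n = %d, within +/-1 SD: %.1f%%, mean %.4f, sd %.4f\n",
              length(x$residuals), 100 * x$fraction_within_1sd, x$mean, x$sd))
  invisible(x)
}

#' Cross-stage validation of a fitted model
#'
#' Scores a fitted model on an external dataset - typically a different
#' phenological stage than it was trained on - returning the Eq-style metrics,
#' residual diagnostics, and the ordinary-least-squares slope of predicted on
#' observed values (slope 1 means no amplitude compression).
#'
#' @param model a `model_bundle` (see [rf_fit()], [svm_fit()], [cnn_fit()],
#'   [pso_cnn_fit()]).
#' @param x external predictors: a [spectra_set()] on the full grid (the
#'   model's stored wavelengths are extracted, erroring if any band is
#'   missing) or a matrix already restricted to the model's features.
#' @param y external observed values.
#' @return A list with `metrics`, `diagnostics`, `slope`, and `predictions`.
#' @export
cross_stage_validate <- function(model, x, y) {
  X <- if (inherits(x, "spectra_set")) {
    if (is.null(model$wavelengths))
      stop("model carries no wavelengths; pass a feature matrix instead")
    idx <- tryCatch(wavelength_index(x, model$wavelengths),
                    error = function(e)
                      stop("external spectra are missing model bands: ",
                           conditionMessage(e)))
    x$reflectance[, idx, drop = FALSE]
  } else as.matrix(x)
  pred <- predict(model, X)
  list(metrics = compute_metrics(y, pred),
       diagnostics = residual_diagnostics(y, pred),
       slope = unname(coef(lm(pred ~ y))[2]),
       predictions = pred)
}
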