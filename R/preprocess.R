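#' Savitzky-Golay kernel
#'
#' Least-squares polynomial filter weights for a symmetric window of
#' `2 * half_width + 1` points: the fitted polynomial of order `poly_order`
#' over the window, evaluated (or differentiated `deriv_order` times) at the
#' window centre. For `deriv_order = 0` the weights sum to one, so constants
#' pass through unchanged.
#'
#' @param half_width window half width `w` in points (full window `2w + 1`).
#' @param poly_order polynomial order; must satisfy `2w + 1 > poly_order`.
#' @param deriv_order derivative order (0 = smoothing, 2 = second derivative).
#' @return An object of class `sg_kernel` holding the central weights.
#' @export
sg_kernel <- function(half_width, poly_order = 2, deriv_order = 0) {
  w <- as.integer(half_width)
  if (2 * w + 1 <= poly_order)
    stop("window (", 2 * w + 1, " points) must exceed poly_order (", poly_order, ")")
  if (deriv_order > poly_order)
    stop("deriv_order cannot exceed poly_order")
  coefficients <- sg_weights(-w:w, poly_order, deriv_order)
  structure(list(half_width = w, poly_order = poly_order,
                 deriv_order = deriv_order, coefficients = coefficients,
                 normalization = 1),
            class = "sg_kernel")
}

# least-squares fit weights over arbitrary integer offsets, evaluated at 0
sg_weights <- function(offsets, poly_order, deriv_order) {
  A <- outer(offsets, 0:poly_order, `^`)
  pinv <- solve(crossprod(A), t(A))
  pinv[deriv_order + 1, ] * factorial(deriv_order)
}

# apply an SG transform to every row of a matrix; truncated-window re-fit at
# the edges so no fabricated data enters the band ends
sg_apply <- function(X, half_width, poly_order, deriv_order) {
  m <- ncol(X)
  w <- half_width
  if (m < 2 * w + 1)
    stop("window (", 2 * w + 1, " points) wider than spectrum (", m, " points)")
  cf <- sg_weights(-w:w, poly_order, deriv_order)
  out <- matrix(0, nrow(X), m)
  interior <- (w + 1):(m - w)
  for (j in seq_along(cf))
    out[, interior] <- out[, interior] + cf[j] * X[, interior + (j - w - 1)]
  for (t in seq_len(w)) { # left edge: window truncated to 1..t+w
    cf_t <- sg_weights((1 - t):w, poly_order, deriv_order)
    out[, t] <- X[, 1:(t + w), drop = FALSE] %*% cf_t
    cf_r <- sg_weights(-w:(t - 1), poly_order, deriv_order)
    out[, m - t + 1] <- X[, (m - t + 1 - w):m, drop = FALSE] %*% cf_r
  }
  out
}

#' Savitzky-Golay smoothing
#'
#' Replaces each point by the value of the least-squares polynomial fitted
#' over its moving window. Boundary points are re-fitted on truncated windows.
#'
#' @param x a [spectra_set()].
#' @param window odd full window width in points (default 15).
#' @param poly_order polynomial order (default 2).
#' @return A smoothed `spectra_set` on the same grid.
#' @export
sg_smooth <- function(x, window = 15, poly_order = 2) {
  stopifnot(inherits(x, "spectra_set"))
  if (window %% 2 == 0) stop("`window` must be odd")
  w <- (window - 1) / 2
  spectra_set(sg_apply(x$reflectance, w, poly_order, 0),
              x$wavelengths, x$sample_ids, units = x$units)
}

#' Savitzky-Golay second derivative
#'
#' Second-derivative transform via the SG kernel with `deriv_order = 2`,
#' scaled by the squared grid spacing so the output is in units of the input
#' per nm squared. Requires a uniform wavelength grid.
#'
#' @inheritParams sg_smooth
#' @return A `spectra_set` of second derivatives.
#' @export
second_derivative <- function(x, window = 15, poly_order = 2) {
  stopifnot(inherits(x, "spectra_set"))
  if (window %% 2 == 0) stop("`window` must be odd")
  if (poly_order < 2) stop("second derivative needs poly_order >= 2")
  dl <- diff(x$wavelengths)
  if (diff(range(dl)) > 1e-8 * mean(dl))
    stop("non-uniform wavelength grid; resample to a constant step first")
  w <- (window - 1) / 2
  d2 <- sg_apply(x$reflectance, w, poly_order, 2) / mean(dl)^2
  spectra_set(d2, x$wavelengths, x$sample_ids,
              units = paste0(x$units, "/nm^2"))
}

#' Savitzky-Golay smoothing followed by second derivative
#'
#' The default preprocessing chain for modelling: smooth, then differentiate
#' twice, both with the same window and polynomial order.
#'
#' @inheritParams sg_smooth
#' @return A `spectra_set` of second derivatives of the smoothed spectra.
#' @export
sg_second_derivative <- function(x, window = 15, poly_order = 2) {
  second_derivative(sg_smooth(x, window, poly_order), window, poly_order)
}

#' Multiplicative scatter correction
#'
#' Regresses each spectrum on a reference spectrum by ordinary least squares,
#' `R_i = k1 * reference + b_i`, and returns `(R_i - b_i) / k1`. The reference
#' defaults to the mean spectrum of `x`; inside modelling it must be computed
#' from training samples only (pass the training-set reference explicitly when
#' correcting test spectra).
#'
#' @param x a [spectra_set()].
#' @param reference `"mean"` or a numeric vector of length `ncol(x)`.
#' @return A list with `spectra` (the corrected `spectra_set`) and `model`
#'   (class `msc_model`: the reference and the per-sample offset/slope).
#' @export
msc <- function(x, reference = "mean") {
  stopifnot(inherits(x, "spectra_set"))
  R <- x$reflectance
  ref <- if (identical(reference, "mean")) colMeans(R) else as.numeric(reference)
  if (length(ref) != ncol(R)) stop("reference length does not match spectrum length")
  if (any(!is.finite(ref)) || var(ref) == 0)
    stop("reference must be finite and non-constant")
  rc <- ref - mean(ref)
  slope <- as.numeric(R %*% rc) / sum(rc^2)
  offset <- rowMeans(R) - slope * mean(ref)
  bad <- abs(slope) < 1e-12
  if (any(bad))
    stop("MSC slope is zero for sample(s): ",
         paste(x$sample_ids[bad], collapse = ", "))
  corrected <- (R - offset) / slope
  list(
    spectra = spectra_set(corrected, x$wavelengths, x$sample_ids, units = x$units),
    model = structure(list(reference = ref,
                           coefficients = data.frame(sample_id = x$sample_ids,
                                                     offset = offset,
                                                     slope = slope)),
                      class = "msc_model")
  )
}

#' Standard normal variate transform
#'
#' Centers each spectrum by its own mean and scales by its own standard
#' deviation (n - 1 denominator), removing per-sample scaling effects.
#'
#' @param x a [spectra_set()].
#' @return The transformed `spectra_set` (unitless rows with mean 0, sd 1).
#' @export
snv <- function(x) {
  stopifnot(inherits(x, "spectra_set"))
  if (ncol(x$reflectance) < 2) stop("SNV needs at least 2 wavelengths")
  mu <- rowMeans(x$reflectance)
  s <- apply(x$reflectance, 1, sd)
  bad <- s == 0
  if (any(bad))
    stop("constant spectrum, SNV undefined for sample(s): ",
         paste(x$sample_ids[bad], collapse = ", "))
  spectra_set((x$reflectance - mu) / s, x$wavelengths, x$sample_ids,
              units = "snv")
}

#' Per-wavelength Pearson correlation with nitrogen
#'
#' Correlation screening of each wavelength column against the response.
#' Zero-variance columns get a correlation of 0 with a warning.
#'
#' @param x a [spectra_set()].
#' @param y numeric response (nitrogen %), one value per sample.
#' @return Numeric vector of correlations, named by wavelength.
#' @export
pearson_by_wavelength <- function(x, y) {
  stopifnot(inherits(x, "spectra_set"))
  if (length(y) != nrow(x$reflectance)) stop("y length does not match samples")
  if (length(y) < 3) stop("need at least 3 samples for correlation screening")
  sds <- apply(x$reflectance, 2, sd)
  r <- rep(0, ncol(x$reflectance))
  ok <- sds > 0
  if (any(!ok))
    warning(sum(!ok), " zero-variance wavelength column(s); r reported as 0")
  r[ok] <- as.numeric(cor(x$reflectance[, ok, drop = FALSE], y))
  names(r) <- wl_names(x$wavelengths)
  r
}

#' Apply a named preprocessing chain
#'
#' @param x a [spectra_set()].
#' @param method one of `"sg"`, `"sg-sd"`, `"sg-msc"`, `"sg-snv"`, `"none"`.
#' @param window,poly_order SG settings.
#' @param msc_reference reference spectrum for the MSC step (`"mean"` or vector).
#' @return The preprocessed `spectra_set`.
#' @export
preprocess <- function(x, method = c("sg-sd", "sg", "sg-msc", "sg-snv", "none"),
                       window = 15, poly_order = 2, msc_reference = "mean") {
  method <- match.arg(method)
  switch(method,
         "none"   = x,
         "sg"     = sg_smooth(x, window, poly_order),
         "sg-sd"  = sg_second_derivative(x, window, poly_order),
         "sg-msc" = msc(sg_smooth(x, window, poly_order), msc_reference)$spectra,
         "sg-snv" = snv(sg_smooth(x, window, poly_order)))
}
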