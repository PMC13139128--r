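#' Nitrogen distribution for a phenological stage
#'
#' Summary statistics of leaf nitrogen content (% dry mass) used to draw
#' synthetic samples: a normal distribution truncated to the observed range.
#'
#' @param mean,sd mean and standard deviation (% N).
#' @param lower,upper observed minimum and maximum (% N); the truncation bounds.
#' @param n default number of samples for the stage.
#' @return An object of class `nitrogen_distribution`.
#' @export
nitrogen_distribution <- function(mean, sd, lower, upper, n) {
  if (!(lower < mean && mean < upper))
    stop("invalid nitrogen distribution: need lower < mean < upper, got [",
         lower, ", ", mean, ", ", upper, "]")
  if (sd <= 0) stop("invalid nitrogen distribution: sd must be > 0")
  if (n < 2) stop("invalid nitrogen distribution: n must be >= 2")
  structure(list(mean = mean, sd = sd, lower = lower, upper = upper, n = n),
            class = "nitrogen_distribution")
}

#' Stage presets for apple-leaf nitrogen
#'
#' Descriptive statistics of apple-leaf nitrogen content at the two
#' phenological stages the pipeline models: the new-shoot-stop-growing stage
#' (NSS; n = 125, mean 2.479 % N, sd 0.201, range 2.035-2.873) and the
#' autumn-shoot-stop-growing stage (ASS; n = 118, mean 2.795 % N, sd 0.248,
#' range 2.235-3.752).
#'
#' @return A `nitrogen_distribution`.
#' @export
nss_distribution <- function() nitrogen_distribution(2.479, 0.201, 2.035, 2.873, 125)

#' @rdname nss_distribution
#' @export
ass_distribution <- function() nitrogen_distribution(2.795, 0.248, 2.235, 3.752, 118)

#' Draw nitrogen values from a truncated normal
#'
#' Inverse-CDF sampling of a normal(mean, sd) truncated to `[lower, upper]`;
#' deterministic given `seed`.
#'
#' @param dist a [nitrogen_distribution()].
#' @param n number of draws; defaults to `dist$n`.
#' @param seed integer seed.
#' @return Numeric vector of length `n`, all values inside `[lower, upper]`.
#' @export
sample_nitrogen <- function(dist, n = dist$n, seed = NULL) {
  stopifnot(inherits(dist, "nitrogen_distribution"))
  with_seed(seed, {
    a <- pnorm((dist$lower - dist$mean) / dist$sd)
    b <- pnorm((dist$upper - dist$mean) / dist$sd)
    u <- runif(n)
    dist$mean + dist$sd * qnorm(a + u * (b - a))
  })
}

#' Closed-form moments of a truncated normal
#'
#' Mean and standard deviation of a normal(mean, sd) truncated to
#' `[lower, upper]` (standard truncated-normal moment formulas); used to
#' calibrate and test the generator.
#'
#' @param dist a [nitrogen_distribution()].
#' @return A list with `mean` and `sd`.
#' @export
truncnorm_moments <- function(dist) {
  a <- (dist$lower - dist$mean) / dist$sd
  b <- (dist$upper - dist$mean) / dist$sd
  z <- pnorm(b) - pnorm(a)
  m <- dist$mean + dist$sd * (dnorm(a) - dnorm(b)) / z
  v <- dist$sd^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / z -
                      ((dnorm(a) - dnorm(b)) / z)^2)
  list(mean = m, sd = sqrt(v))
}

#' Default absorption-feature table for apple-leaf reflectance
#'
#' Gaussian absorption profiles superimposed on the leaf continuum. Each row
#' carries the band centre (nm), width (Gaussian sigma, nm), base optical
#' depth, and loadings of the depth on the four per-sample biochemical
#' latents: chlorophyll (pigment bands), water, protein, and structural
#' carbohydrates. Pigment and protein depths increase with nitrogen (their
#' latents are positively tied to nitrogen), structural-carbohydrate depth
#' decreases with nitrogen.
#'
#' @return A data.frame with columns `center`, `width`, `depth`, `coef_chl`,
#'   `coef_water`, `coef_protein`, `coef_structural`.
#' @export
absorption_features_default <- function() {
  data.frame(
    center = c(430, 460, 680, 970, 1200, 1450, 1940, 2045, 2180, 2340, 2385),
    width  = c( 25,  25,  22,  35,   45,   55,   70,   14,   16,   14,   12),
    depth  = c(1.6, 1.5, 1.8, 0.06, 0.12, 0.95, 1.35, 0.12, 0.14, 0.10, 0.08),
    coef_chl        = c(0.25, 0.22, 0.30, 0, 0, 0, 0, 0, 0, 0, 0),
    coef_water      = c(0, 0, 0, 0.02, 0.04, 0.12, 0.15, 0, 0, 0, 0),
    coef_protein    = c(0, 0, 0, 0, 0, 0, 0, 0.09, 0.10, 0, 0),
    coef_structural = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0.06, 0.05)
  )
}

#' Generator configuration for synthetic leaf spectra
#'
#' Bundles every knob of the synthetic-spectra generator: the wavelength grid,
#' the stage's nitrogen distribution, the absorption-feature table, per-sample
#' multiplicative/additive scatter perturbations, a wavelength-dependent noise
#' floor (edge-inflated over the outer `edge_blend_nm`), and the correlations
#' tying the biochemical latents to nitrogen.
#'
#' @param stage `"NSS"` or `"ASS"`; picks the nitrogen preset and, for ASS, a
#'   structural-carbohydrate depth offset emulating cross-stage covariate shift.
#' @param wavelengths wavelength grid in nm (default 400-2500, 1 nm step).
#' @param nitrogen a [nitrogen_distribution()]; defaults to the stage preset.
#' @param absorption_features feature table, see [absorption_features_default()].
#' @param scatter_slope_sd,scatter_offset_sd standard deviations of the
#'   per-sample multiplicative and additive scatter perturbations.
#' @param noise_sd_core,noise_sd_edge reflectance noise sd in the grid core and
#'   at the grid edges (must be in `[0, 0.05)`).
#' @param edge_blend_nm width (nm) of the linear core-to-edge noise blend.
#' @param latent_correlations named numeric vector of correlations between
#'   nitrogen and the chlorophyll, water, protein, and structural latents.
#' @param structural_depth_offset additive offset applied to the base depth of
#'   structural-carbohydrate bands (ASS default 0.03, NSS 0).
#' @param seed integer seed.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(stage = c("NSS", "ASS"),
                             wavelengths = 400:2500,
                             nitrogen = NULL,
                             absorption_features = absorption_features_default(),
                             scatter_slope_sd = 0.04,
                             scatter_offset_sd = 0.01,
                             noise_sd_core = 0.002,
                             noise_sd_edge = 0.008,
                             edge_blend_nm = 200,
                             latent_correlations = c(chlorophyll = 0.9,
                                                     water = 0.3,
                                                     protein = 0.9,
                                                     structural = -0.7),
                             structural_depth_offset = NULL,
                             seed = 1L) {
  stage <- match.arg(stage)
  if (any(diff(wavelengths) <= 0)) stop("wavelength grid must be strictly increasing")
  if (any(absorption_features$width <= 0)) stop("all feature widths must be > 0")
  if (noise_sd_core < 0 || noise_sd_core >= 0.05 ||
      noise_sd_edge < 0 || noise_sd_edge >= 0.05)
    stop("noise sds must lie in [0, 0.05)")
  need <- c("chlorophyll", "water", "protein", "structural")
  if (!all(need %in% names(latent_correlations)))
    stop("latent_correlations must name: ", paste(need, collapse = ", "))
  if (any(abs(latent_correlations) > 1)) stop("latent correlations must be in [-1, 1]")
  nitrogen <- nitrogen %||%
    (if (stage == "NSS") nss_distribution() else ass_distribution())
  structural_depth_offset <- structural_depth_offset %||%
    (if (stage == "ASS") 0.03 else 0)
  structure(
    list(stage = stage, wavelengths = as.numeric(wavelengths),
         nitrogen = nitrogen, absorption_features = absorption_features,
         scatter_slope_sd = scatter_slope_sd,
         scatter_offset_sd = scatter_offset_sd,
         noise_sd_core = noise_sd_core, noise_sd_edge = noise_sd_edge,
         edge_blend_nm = edge_blend_nm,
         latent_correlations = latent_correlations[need],
         structural_depth_offset = structural_depth_offset,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

leaf_continuum <- function(wl) {
  0.13 + 0.38 * stats::plogis((wl - 705) / 16) -
    0.18 * stats::plogis((wl - 1500) / 400)
}

edge_noise_sd <- function(wl, core, edge, blend) {
  lo <- min(wl); hi <- max(wl)
  w <- pmax(0, pmax(1 - (wl - lo) / blend, 1 - (hi - wl) / blend))
  core + (edge - core) * w
}

#' Generate synthetic leaf reflectance spectra
#'
#' Builds `length(nitrogen)` reflectance spectra on the configured grid:
#' a leaf continuum (low visible shelf, logistic red edge near 700 nm, NIR
#' plateau, gentle SWIR decline) attenuated by Gaussian absorption features
#' whose optical depths are linear in per-sample biochemical latents tied to
#' nitrogen, then perturbed by per-sample affine scatter and edge-inflated
#' noise, and clipped to (0.001, 0.999). Reproducible given `config$seed`.
#'
#' @param nitrogen numeric vector of nitrogen values (% N), length >= 2.
#' @param config a [generator_config()].
#' @return An object of class `synthetic_dataset`: list with `spectra`
#'   (a [spectra_set()]), `nitrogen`, `latents` (per-sample latent table) and
#'   `provenance` (config + seed).
#' @export
generate_spectra <- function(nitrogen, config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  n <- length(nitrogen)
  if (n < 2) stop("need at least 2 nitrogen values")
  wl <- config$wavelengths
  feats <- config$absorption_features
  if (any(feats$center < min(wl) | feats$center > max(wl)))
    stop("wavelength grid does not cover all absorption feature centers: ",
         paste(feats$center[feats$center < min(wl) | feats$center > max(wl)],
               collapse = ", "), " nm")

  with_seed(config$seed, {
    z <- (nitrogen - config$nitrogen$mean) / config$nitrogen$sd
    rho <- config$latent_correlations
    lat <- vapply(names(rho), function(nm) {
      rho[[nm]] * z + sqrt(1 - rho[[nm]]^2) * rnorm(n)
    }, numeric(n))
    if (n == 1) lat <- matrix(lat, nrow = 1, dimnames = list(NULL, names(rho)))
    colnames(lat) <- names(rho)

    base_depth <- feats$depth +
      ifelse(feats$coef_structural > 0, config$structural_depth_offset, 0)
    # n x k matrix of per-sample band depths, linear in the latents
    depths <- matrix(base_depth, n, nrow(feats), byrow = TRUE) +
      lat[, "chlorophyll"] %o% feats$coef_chl +
      lat[, "water"] %o% feats$coef_water +
      lat[, "protein"] %o% feats$coef_protein +
      lat[, "structural"] %o% feats$coef_structural
    depths[depths < 0] <- 0

    # k x m Gaussian profiles
    G <- t(vapply(seq_len(nrow(feats)), function(k) {
      exp(-((wl - feats$center[k])^2) / (2 * feats$width[k]^2))
    }, numeric(length(wl))))
    continuum <- leaf_continuum(wl)
    clean <- exp(-depths %*% G) * matrix(continuum, n, length(wl), byrow = TRUE)

    a_s <- 1 + rnorm(n, 0, config$scatter_slope_sd)
    b_s <- rnorm(n, 0, config$scatter_offset_sd)
    noise_sd <- edge_noise_sd(wl, config$noise_sd_core, config$noise_sd_edge,
                              config$edge_blend_nm)
    eps <- matrix(rnorm(n * length(wl)), n, length(wl)) *
      matrix(noise_sd, n, length(wl), byrow = TRUE)

    refl <- clip(clean * a_s + b_s + eps, 0.001, 0.999)
    structure(
      list(spectra = spectra_set(refl, wl),
           nitrogen = as.numeric(nitrogen),
           latents = as.data.frame(lat),
           provenance = list(config = config, seed = config$seed, n = n)),
      class = "synthetic_dataset"
    )
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> stage %s: %d samples, %d wavelengths; N %% in [%.3f, %.3f]\n",
              x$provenance$config$stage, length(x$nitrogen),
              length(x$spectra$wavelengths), min(x$nitrogen), max(x$nitrogen)))
  invisible(x)
}

#' Simulate a full stage dataset
#'
#' Convenience wrapper: draws nitrogen from the stage's truncated normal and
#' generates the matching spectra. Nitrogen draws and spectra use seeds
#' derived from `seed` so the two sub-streams are independent.
#'
#' @param stage `"NSS"` or `"ASS"`.
#' @param n number of samples; defaults to the stage preset (125 NSS, 118 ASS).
#' @param seed integer seed.
#' @param config optional [generator_config()]; its seed is overridden.
#' @return A `synthetic_dataset`.
#' @export
simulate_dataset <- function(stage = c("NSS", "ASS"), n = NULL, seed = 1L,
                             config = NULL) {
  stage <- match.arg(stage)
  config <- config %||% generator_config(stage = stage)
  config$seed <- as.integer(stage_seed(seed, paste0("spectra_", stage)))
  n <- n %||% config$nitrogen$n
  nitrogen <- sample_nitrogen(config$nitrogen, n = n,
                              seed = stage_seed(seed, paste0("nitrogen_", stage)))
  generate_spectra(nitrogen, config)
}
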