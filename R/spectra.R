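#' Construct a spectra set
#'
#' The basic container used throughout the package: an `n x m` matrix of
#' reflectance (or transformed reflectance) with an explicit, strictly
#' increasing wavelength grid and per-sample identifiers.
#'
#' @param reflectance numeric matrix, samples in rows, wavelengths in columns.
#' @param wavelengths numeric vector of wavelengths in nm, strictly increasing,
#'   length `ncol(reflectance)`.
#' @param sample_ids character vector of sample labels; defaults to
#'   `"s0001", "s0002", ...`.
#' @param units character label for the values held (informational only),
#'   e.g. `"reflectance"` or `"reflectance/nm^2"` after a second derivative.
#' @return An object of class `spectra_set` with elements `reflectance`,
#'   `wavelengths`, `sample_ids` and `units`.
#' @export
spectra_set <- function(reflectance, wavelengths,
                        sample_ids = NULL, units = "reflectance") {
  reflectance <- as.matrix(reflectance)
  storage.mode(reflectance) <- "double"
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) != ncol(reflectance))
    stop("`wavelengths` length (", length(wavelengths),
         ") does not match ncol(reflectance) (", ncol(reflectance), ")")
  if (any(diff(wavelengths) <= 0))
    stop("`wavelengths` must be strictly increasing")
  if (anyNA(reflectance) || any(!is.finite(reflectance)))
    stop("reflectance contains missing or non-finite values")
  if (is.null(sample_ids))
    sample_ids <- sprintf("s%04d", seq_len(nrow(reflectance)))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(reflectance))
    stop("`sample_ids` length does not match nrow(reflectance)")
  if (anyDuplicated(sample_ids))
    stop("`sample_ids` must be unique")
  rownames(reflectance) <- sample_ids
  colnames(reflectance) <- wl_names(wavelengths)
  structure(
    list(reflectance = reflectance, wavelengths = wavelengths,
         sample_ids = sample_ids, units = units),
    class = "spectra_set"
  )
}

wl_names <- function(wavelengths) sprintf("r%04d", round(wavelengths))

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("<spectra_set> %d samples x %d wavelengths (%g-%g nm), units: %s\n",
              nrow(x$reflectance), length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths), x$units))
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$reflectance)

#' Subset a spectra set by sample and/or wavelength
#'
#' @param x a `spectra_set`.
#' @param i sample index (row) selector.
#' @param j wavelength index (column) selector.
#' @param ... ignored.
#' @return A `spectra_set` restricted to the requested rows/columns.
#' @export
`[.spectra_set` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$reflectance))
  if (missing(j)) j <- seq_along(x$wavelengths)
  spectra_set(x$reflectance[i, j, drop = FALSE], x$wavelengths[j],
              x$sample_ids[i], units = x$units)
}

#' Locate wavelength grid indices for requested wavelengths
#'
#' @param x a `spectra_set`.
#' @param nm numeric vector of wavelengths (nm) to look up.
#' @param tol maximal absolute mismatch (nm) tolerated when matching.
#' @return Integer indices into `x$wavelengths`.
#' @export
wavelength_index <- function(x, nm, tol = 0.5) {
  idx <- vapply(nm, function(w) which.min(abs(x$wavelengths - w)), integer(1))
  miss <- abs(x$wavelengths[idx] - nm) > tol
  if (any(miss))
    stop("wavelengths not on the grid: ", paste(nm[miss], collapse = ", "), " nm")
  idx
}

#' Write a dataset to a wide CSV with a JSON sidecar
#'
#' Writes one row per sample (`sample_id`, `nitrogen`, then one reflectance
#' column per wavelength, named `r0400 ... r2500`). Generation provenance
#' (configuration and seed), when present, is written next to the CSV as
#' `<path>.json` so the dataset can be regenerated exactly.
#'
#' @param ds a `synthetic_dataset` (see [generate_spectra()]) or a list with
#'   elements `spectra` (a `spectra_set`) and `nitrogen` (numeric vector).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @seealso [read_dataset()]
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds$spectra, "spectra_set"))
  x <- ds$spectra
  df <- data.frame(sample_id = x$sample_ids, nitrogen = as.numeric(ds$nitrogen),
                   x$reflectance, check.names = FALSE,
                   stringsAsFactors = FALSE)
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok))
    stop("cannot write dataset to '", path, "': ", conditionMessage(ok))
  if (!is.null(ds$provenance)) {
    sidecar <- paste0(path, ".json")
    jsonlite::write_json(provenance_json(ds$provenance), sidecar,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

provenance_json <- function(prov) {
  cfg <- prov$config
  list(
    stage = cfg$stage,
    seed = prov$seed,
    n = prov$n,
    wavelength_grid = list(from = min(cfg$wavelengths), to = max(cfg$wavelengths),
                           by = unique(diff(cfg$wavelengths))[1]),
    nitrogen = cfg$nitrogen[c("mean", "sd", "lower", "upper", "n")],
    absorption_features = cfg$absorption_features,
    scatter_slope_sd = cfg$scatter_slope_sd,
    scatter_offset_sd = cfg$scatter_offset_sd,
    noise_sd_core = cfg$noise_sd_core,
    noise_sd_edge = cfg$noise_sd_edge,
    edge_blend_nm = cfg$edge_blend_nm,
    latent_correlations = cfg$latent_correlations,
    structural_depth_offset = cfg$structural_depth_offset
  )
}

#' Read a dataset written by [write_dataset()]
#'
#' @param path CSV path.
#' @return A list with `spectra` (a `spectra_set`), `nitrogen`, and, when the
#'   JSON sidecar is present, `provenance` (the parsed sidecar).
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("no such file: '", path, "'")
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  wl_cols <- grep("^r[0-9]{4}$", names(df))
  wavelengths <- as.numeric(sub("^r", "", names(df)[wl_cols]))
  spectra <- spectra_set(as.matrix(df[, wl_cols, drop = FALSE]), wavelengths,
                         sample_ids = df$sample_id)
  out <- list(spectra = spectra, nitrogen = df$nitrogen)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar))
    out$provenance <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  out
}
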