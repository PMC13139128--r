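#' Successive projections algorithm (SPA)
#'
#' Forward selection minimising collinearity: starting from each candidate
#' column in turn, the algorithm repeatedly appends the column with the
#' largest norm after orthogonal projection onto the complement of the span of
#' the columns already chosen (modified Gram-Schmidt). Every (start, length)
#' prefix is then scored by multiple-linear-regression RMSE under the chosen
#' validation scheme, and the subset with minimal RMSE is returned.
#'
#' @param X numeric matrix (n x p), training rows.
#' @param y numeric response.
#' @param candidate_indices columns of `X` admitted to the search (typically
#'   the CARS winner set); defaults to all columns.
#' @param max_vars maximal subset size (must be `<= min(30, n - 2)`).
#' @param validation `"cv"` (k-fold CV on the training rows, the default) or
#'   `"holdout"` (score on `X_val`, `y_val` - the protocol that evaluates on an
#'   external set).
#' @param folds CV folds when `validation = "cv"`.
#' @param X_val,y_val held-out data when `validation = "holdout"`.
#' @param seed integer seed (fold assignment).
#' @return An object of class `selected_wavelengths`: `indices` (ordered as
#'   selected), `rmse` (the minimised validation RMSE), `rmse_calibration`
#'   (training RMSE of the same subset), `start`, and the full chain table.
#' @export
spa_select <- function(X, y, candidate_indices = NULL, max_vars = 15,
                       validation = c("cv", "holdout"), folds = 5,
                       X_val = NULL, y_val = NULL, seed = NULL) {
  validation <- match.arg(validation)
  X <- as.matrix(X)
  n <- nrow(X)
  cand <- sort(candidate_indices %||% seq_len(ncol(X)))
  if (max_vars > min(30, n - 2))
    stop("max_vars must be <= min(30, n - 2) = ", min(30, n - 2))
  max_vars <- min(max_vars, length(cand))
  if (validation == "holdout" && (is.null(X_val) || is.null(y_val)))
    stop("holdout validation needs X_val and y_val")

  Xc <- X[, cand, drop = FALSE]
  chains <- lapply(seq_along(cand), function(s)
    spa_chain(Xc, start = s, max_len = max_vars))

  fold_id <- with_seed(seed, sample(rep(seq_len(folds), length.out = n)))
  score <- function(cols) {
    Xs <- X[, cols, drop = FALSE]
    if (validation == "cv") {
      pred <- numeric(n)
      for (k in seq_len(folds)) {
        hold <- fold_id == k
        fit <- stats::lm.fit(cbind(1, Xs[!hold, , drop = FALSE]), y[!hold])
        cf <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
        pred[hold] <- cbind(1, Xs[hold, , drop = FALSE]) %*% cf
      }
      sqrt(mean((y - pred)^2))
    } else {
      fit <- stats::lm.fit(cbind(1, Xs), y)
      cf <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
      pred <- cbind(1, as.matrix(X_val)[, cols, drop = FALSE]) %*% cf
      sqrt(mean((y_val - pred)^2))
    }
  }

  best <- list(rmse = Inf)
  for (s in seq_along(chains)) {
    ch <- chains[[s]]
    for (L in seq_along(ch$chain)) {
      cols <- cand[ch$chain[seq_len(L)]]
      r <- score(cols)
      if (r < best$rmse - 1e-15)
        best <- list(rmse = r, cols = cols, start = cand[s], length = L)
    }
  }
  fit <- stats::lm.fit(cbind(1, X[, best$cols, drop = FALSE]), y)
  rmse_cal <- sqrt(mean(fit$residuals^2))
  structure(
    list(indices = best$cols, rmse = best$rmse, rmse_calibration = rmse_cal,
         start = best$start, n_selected = best$length,
         validation = validation, chains = chains, candidates = cand),
    class = "selected_wavelengths"
  )
}

#' Successive projection chain from one starting column
#'
#' @param X numeric matrix whose columns are the candidates.
#' @param start starting column index (into `X`).
#' @param max_len maximal chain length.
#' @param tol residual-norm threshold below which the chain is truncated.
#' @return A list with `chain` (column indices in selection order) and
#'   `residual_norms` (the projection residual norm of each pick).
#' @export
spa_chain <- function(X, start, max_len, tol = 1e-10) {
  X <- as.matrix(X)
  p <- ncol(X)
  R <- X                      # residuals after projecting off selected columns
  chain <- integer(0)
  norms <- numeric(0)
  pick <- start
  for (step in seq_len(min(max_len, p))) {
    nrm <- sqrt(sum(R[, pick]^2))
    if (nrm < tol) break      # rank deficiency: truncate the chain
    chain <- c(chain, pick)
    norms <- c(norms, nrm)
    u <- R[, pick] / nrm
    R <- R - u %o% as.numeric(crossprod(R, u))
    if (length(chain) == min(max_len, p)) break
    rn <- sqrt(colSums(R^2))
    rn[chain] <- -Inf
    if (max(rn) < tol) break
    pick <- which.max(rn)     # which.max takes the lowest index on ties
  }
  list(chain = chain, residual_norms = norms)
}

#' Hybrid CARS-SPA wavelength selection
#'
#' Runs [cars_select()] on the (preprocessed) spectra and refines the winning
#' variable set with [spa_select()]. The full CARS trace is kept on the result
#' for audit.
#'
#' @param x a [spectra_set()] (typically SG second-derivative spectra,
#'   training rows only) or a numeric matrix.
#' @param y numeric response (nitrogen %).
#' @param max_vars maximal SPA subset size (default 15).
#' @param n_runs,subset_fraction,folds,max_components CARS settings, see
#'   [cars_select()].
#' @param validation,X_val,y_val SPA scoring scheme, see [spa_select()].
#' @param seed integer seed.
#' @return A `selected_wavelengths` object; when `x` is a `spectra_set` it
#'   additionally carries `wavelengths` (nm) and the `cars` trace.
#' @export
cars_spa <- function(x, y, max_vars = 15, n_runs = 50, subset_fraction = 0.8,
                     folds = 5, max_components = 10,
                     validation = c("cv", "holdout"),
                     X_val = NULL, y_val = NULL, seed = NULL) {
  validation <- match.arg(validation)
  X <- if (inherits(x, "spectra_set")) x$reflectance else as.matrix(x)
  trace <- cars_select(X, y, n_runs = n_runs, subset_fraction = subset_fraction,
                       folds = folds, max_components = max_components,
                       seed = stage_seed(seed %||% 0L, "cars"))
  sel <- spa_select(X, y, candidate_indices = trace$selected,
                    max_vars = min(max_vars, length(trace$selected)),
                    validation = validation, folds = folds,
                    X_val = X_val, y_val = y_val,
                    seed = stage_seed(seed %||% 0L, "spa"))
  sel$cars <- trace
  if (inherits(x, "spectra_set"))
    sel$wavelengths <- x$wavelengths[sel$indices]
  sel
}

#' @export
print.selected_wavelengths <- function(x, ...) {
  cat(sprintf("<selected_wavelengths> %d variables (start %d, %s RMSE %.4f)\n",
              length(x$indices), x$start, x$validation, x$rmse))
  if (!is.null(x$wavelengths))
    cat("  nm:", paste(round(x$wavelengths), collapse = ", "), "\n")
  invisible(x)
}

#' Reference characteristic wavelengths for apple-leaf nitrogen
#'
#' The 15-band characteristic wavelength set reported for apple-leaf nitrogen
#' inversion from SG second-derivative spectra (CARS followed by SPA), shipped
#' as a fixture so models can be built on the published band set without
#' re-running selection.
#'
#' @return A list with `wavelengths` (nm), `n_cars` (size of the CARS winner
#'   set it was refined from), and `rmse` (the reported minimal RMSE).
#' @export
reference_wavelengths <- function() {
  path <- system.file("extdata", "apple_leaf_wavelengths.json",
                      package = "nitrospec", mustWork = TRUE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}
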