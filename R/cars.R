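#' Competitive adaptive reweighted sampling (CARS)
#'
#' Monte-Carlo PLS-based wavelength elimination. At run `i` of `n_runs`, a
#' PLS1 model is fitted on a random `subset_fraction` of the samples using the
#' currently retained variables; variables are weighted by their normalised
#' absolute regression coefficients `w_j = |b_j| / sum |b_j|`; an exponentially
#' decreasing function (EDF) forces the retained count down to
#' `ceiling(r_i * p)` with `r_i = a * exp(-k * i)`,
#' `a = (p/2)^(1/(N-1))`, `k = log(p/2)/(N-1)` (so all `p` variables survive
#' run 1 and exactly 2 survive run `N`); adaptive reweighted sampling then
#' draws that many variables with replacement with probabilities `w_j`,
#' keeping the unique draws. Each run records the 5-fold RMSECV of PLS on the
#' retained set; the winner is the run with minimal RMSECV.
#'
#' The PLS component count is chosen once, by cross-validation on the full
#' variable set, then capped by the retained-set size inside each run.
#'
#' @param X numeric matrix of predictors (n x p), typically SG second
#'   derivative spectra restricted to training rows.
#' @param y numeric response (nitrogen %).
#' @param n_runs number of Monte-Carlo runs `N` (default 50).
#' @param subset_fraction fraction of samples drawn per run (default 0.8).
#' @param folds CV folds for the per-run RMSECV (default 5).
#' @param max_components PLS component cap (default 10).
#' @param seed integer seed.
#' @return An object of class `cars_trace`: per-run records (`ratio`,
#'   `n_retained`, `rmsecv`, `retained` index sets), the EDF constants, the
#'   winning run, and `selected` (retained variable indices of the winner).
#' @export
cars_select <- function(X, y, n_runs = 50, subset_fraction = 0.8, folds = 5,
                        max_components = 10, seed = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (p < 10) stop("CARS needs at least 10 variables")
  if (n < 10) stop("CARS needs at least 10 samples")
  a_edf <- (p / 2)^(1 / (n_runs - 1))
  k_edf <- log(p / 2) / (n_runs - 1)
  ratios <- a_edf * exp(-k_edf * seq_len(n_runs))

  with_seed(seed, {
    ncomp0 <- pls_rmsecv(X, y, max_components, folds,
                         seed = sample.int(2^31 - 1, 1))$best_ncomp
    retained <- seq_len(p)
    runs <- vector("list", n_runs)
    flagged <- FALSE
    for (i in seq_len(n_runs)) {
      if (length(retained) < 2) { flagged <- TRUE; break }
      sub <- sample(n, round(subset_fraction * n))
      fit <- pls1_fit(X[sub, retained, drop = FALSE], y[sub],
                      min(ncomp0, length(retained), length(sub) - 1))
      b <- fit$coef_path[, fit$ncomp]
      w <- abs(b) / sum(abs(b))
      keep_n <- min(ceiling(ratios[i] * p), length(retained))
      # EDF: forced retention of the top keep_n variables by weight
      ord <- order(w, decreasing = TRUE)
      retained <- retained[ord[seq_len(keep_n)]]
      w <- w[ord[seq_len(keep_n)]]
      # ARS: competitive resampling with replacement, keep unique draws
      draws <- sample(seq_along(retained), keep_n, replace = TRUE,
                      prob = w / sum(w))
      retained <- sort(retained[unique(draws)])
      if (length(retained) < 2) { flagged <- TRUE; break }
      cv <- pls_rmsecv(X[, retained, drop = FALSE], y,
                       min(ncomp0, length(retained)), folds,
                       seed = sample.int(2^31 - 1, 1))
      runs[[i]] <- list(run = i, ratio = ratios[i],
                        n_retained = length(retained),
                        rmsecv = min(cv$rmsecv), retained = retained)
    }
    runs <- runs[!vapply(runs, is.null, logical(1))]
    rmse_all <- vapply(runs, `[[`, numeric(1), "rmsecv")
    winner <- which.min(rmse_all)
    structure(
      list(runs = runs, edf = list(a = a_edf, k = k_edf, ratios = ratios),
           n_runs = n_runs, p = p, ncomp = ncomp0,
           winner = winner, selected = runs[[winner]]$retained,
           rmsecv = rmse_all[winner], flagged = flagged),
      class = "cars_trace"
    )
  })
}

#' @export
print.cars_trace <- function(x, ...) {
  cat(sprintf("<cars_trace> %d runs over %d variables; winner run %d: %d retained, RMSECV %.4f%s\n",
              length(x$runs), x$p, x$winner, length(x$selected), x$rmsecv,
              if (x$flagged) " (terminated early)" else ""))
  invisible(x)
}

#' EDF retention ratios used by CARS
#'
#' @param p number of variables.
#' @param n_runs number of CARS runs.
#' @return Numeric vector `r_i, i = 1..n_runs`.
#' @export
cars_edf_ratios <- function(p, n_runs) {
  a <- (p / 2)^(1 / (n_runs - 1))
  k <- log(p / 2) / (n_runs - 1)
  a * exp(-k * seq_len(n_runs))
}
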