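#' Mahalanobis-distance outlier screening in PCA score space
#'
#' Projects the spectra onto the leading principal components that cover
#' `variance_kept` of the variance (capped at `max_pcs`), computes squared
#' Mahalanobis distances in that score space, and flags samples whose distance
#' exceeds the chi-square `1 - alpha` quantile with as many degrees of freedom
#' as retained components. Single pass; no re-iteration after removal.
#'
#' @param x a [spectra_set()] or numeric matrix (samples in rows).
#' @param variance_kept fraction of variance the retained components must
#'   cover (default 0.95).
#' @param max_pcs cap on the number of components (default 10).
#' @param alpha tail probability of the flagging threshold (default 0.025).
#' @return An object of class `outlier_report`: `flagged` (sample ids),
#'   `flagged_idx`, `distance2` (squared distances), `threshold`, and
#'   `n_components`.
#' @export
mahalanobis_outliers <- function(x, variance_kept = 0.95, max_pcs = 10,
                                 alpha = 0.025) {
  X <- if (inherits(x, "spectra_set")) x$reflectance else as.matrix(x)
  ids <- if (inherits(x, "spectra_set")) x$sample_ids else
    rownames(X) %||% as.character(seq_len(nrow(X)))
  n <- nrow(X)
  if (n <= max_pcs + 1) stop("need n > max_pcs + 1 samples")
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  pos <- ev > max(ev) * 1e-12
  ev <- ev[pos]
  k_var <- which(cumsum(ev) / sum(ev) >= variance_kept)[1]
  k <- min(k_var, max_pcs, sum(pos))
  if (sum(pos) < min(k_var, max_pcs))
    warning("singular covariance: score space reduced to ", sum(pos),
            " informative component(s)")
  scores <- pc$x[, seq_len(k), drop = FALSE]
  d2 <- mahalanobis(scores, colMeans(scores), cov(scores))
  threshold <- qchisq(1 - alpha, df = k)
  flagged <- d2 > threshold
  structure(
    list(flagged = ids[flagged], flagged_idx = which(flagged),
         distance2 = stats::setNames(d2, ids), threshold = threshold,
         n_components = k, alpha = alpha),
    class = "outlier_report"
  )
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("<outlier_report> %d/%d flagged (chi-square df=%d, threshold %.2f)\n",
              length(x$flagged_idx), length(x$distance2), x$n_components,
              x$threshold))
  invisible(x)
}

#' SPXY train/test partitioning
#'
#' Kennard-Stone selection under the joint X-Y distance
#' `d(i, j) = d_x(i, j)/max(d_x) + d_y(i, j)/max(d_y)` with Euclidean `d_x`
#' over the spectra and `|y_i - y_j|` for `d_y`. The training set is seeded
#' with the most distant pair, then grown by repeatedly adding the sample
#' whose minimal distance to the current training set is largest, until
#' `floor(train_fraction * n + 0.5)` samples are selected; the remainder forms
#' the test set. Fully deterministic; ties are broken by the lowest sample
#' index.
#'
#' @param x a [spectra_set()] or numeric matrix.
#' @param y numeric response (nitrogen %), one value per sample.
#' @param train_fraction fraction of samples assigned to training
#'   (default 0.6; 125 samples give a 75/50 split).
#' @return An object of class `data_split` with `train` and `test` index
#'   vectors (sorted), `train_ids`/`test_ids` when ids are available, the
#'   selection `order`, and `method = "SPXY"`.
#' @export
spxy_split <- function(x, y, train_fraction = 0.6) {
  X <- if (inherits(x, "spectra_set")) x$reflectance else as.matrix(x)
  ids <- if (inherits(x, "spectra_set")) x$sample_ids else rownames(X)
  n <- nrow(X)
  if (n < 4) stop("SPXY needs at least 4 samples")
  if (length(y) != n) stop("y length does not match samples")
  if (any(!is.finite(y))) stop("y must be finite")

  dx <- as.matrix(stats::dist(X))
  dy <- abs(outer(y, y, `-`))
  d <- dx / max(dx) + dy / max(dy)

  n_train <- floor(train_fraction * n + 0.5)
  if (n_train < 2 || n_train >= n)
    stop("train_fraction leaves fewer than 2 train or no test samples")

  # seed pair: maximal joint distance, lowest indices on ties
  dimnames(d) <- NULL
  upper <- which(upper.tri(d), arr.ind = TRUE)
  dv <- d[upper]
  best <- upper[which.max(dv), ] # arr.ind order is column-major: lowest indices first
  sel <- sort(as.integer(best))
  min_d <- pmin(d[, sel[1]], d[, sel[2]])
  while (length(sel) < n_train) {
    min_d[sel] <- -Inf
    nxt <- which.max(min_d)    # lowest index wins ties
    sel <- c(sel, as.integer(nxt))
    min_d <- pmin(min_d, d[, nxt])
  }
  train <- sort(sel)
  test <- setdiff(seq_len(n), train)
  structure(
    list(train = train, test = test,
         train_ids = if (!is.null(ids)) ids[train],
         test_ids = if (!is.null(ids)) ids[test],
         order = sel, method = "SPXY", train_fraction = train_fraction),
    class = "data_split"
  )
}

#' Seeded random split (baseline)
#'
#' @param n number of samples.
#' @param train_fraction fraction assigned to training (nearest-integer rule,
#'   as in [spxy_split()]).
#' @param seed integer seed.
#' @return A `data_split` with `method = "random"`.
#' @export
random_split <- function(n, train_fraction = 0.6, seed = NULL) {
  n_train <- floor(train_fraction * n + 0.5)
  train <- sort(with_seed(seed, sample(n, n_train)))
  structure(
    list(train = train, test = setdiff(seq_len(n), train),
         order = train, method = "random", train_fraction = train_fraction,
         seed = seed),
    class = "data_split"
  )
}

#' @export
print.data_split <- function(x, ...) {
  cat(sprintf("<data_split> %s: %d train / %d test\n", x$method,
              length(x$train), length(x$test)))
  invisible(x)
}
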