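#' Fit a PLS1 regression (NIPALS)
#'
#' Single-response partial least squares, the cross-validated regression core
#' that CARS reweights over. Columns are mean-centred (no scaling); the
#' coefficient path for 1..`ncomp` components is retained so cross-validation
#' can score every component count from one fit.
#'
#' @param X numeric matrix (n x p).
#' @param y numeric response (length n).
#' @param ncomp number of latent components.
#' @return An object of class `pls1` with the weight/loading matrices, the
#'   per-component coefficient path (`coef_path`, p x ncomp), and the
#'   training means.
#' @export
pls1_fit <- function(X, y, ncomp) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  ncomp_max <- min(p, n - 1)
  if (ncomp > ncomp_max) {
    warning("ncomp capped at ", ncomp_max)
    ncomp <- ncomp_max
  }
  xbar <- colMeans(X); ybar <- mean(y)
  E <- sweep(X, 2, xbar); f <- y - ybar
  W <- P <- matrix(0, p, ncomp)
  q <- numeric(ncomp)
  a_used <- 0
  for (a in seq_len(ncomp)) {
    wv <- crossprod(E, f)
    nw <- sqrt(sum(wv^2))
    if (nw < 1e-14) break
    wv <- wv / nw
    t_sc <- as.numeric(E %*% wv)
    tt <- sum(t_sc^2)
    if (tt < 1e-14) break
    W[, a] <- wv
    P[, a] <- crossprod(E, t_sc) / tt
    q[a] <- sum(t_sc * f) / tt
    E <- E - tcrossprod(t_sc, P[, a])
    f <- f - t_sc * q[a]
    a_used <- a
  }
  A <- max(a_used, 1)
  coef_path <- matrix(0, p, A)
  for (a in seq_len(a_used)) {
    Wa <- W[, 1:a, drop = FALSE]
    Pa <- P[, 1:a, drop = FALSE]
    coef_path[, a] <- Wa %*% solve(crossprod(Pa, Wa), q[1:a])
  }
  structure(list(ncomp = A, xbar = xbar, ybar = ybar,
                 W = W[, seq_len(A), drop = FALSE],
                 P = P[, seq_len(A), drop = FALSE],
                 q = q[seq_len(A)],
                 coef_path = coef_path),
            class = "pls1")
}

#' @export
coef.pls1 <- function(object, ncomp = object$ncomp, ...) {
  b <- object$coef_path[, min(ncomp, object$ncomp)]
  c(intercept = object$ybar - sum(object$xbar * b), b)
}

#' @export
predict.pls1 <- function(object, newdata, ncomp = object$ncomp, ...) {
  newdata <- as.matrix(newdata)
  if (ncomp == 0) return(rep(object$ybar, nrow(newdata)))
  b <- object$coef_path[, min(ncomp, object$ncomp)]
  as.numeric(sweep(newdata, 2, object$xbar) %*% b) + object$ybar
}

#' Cross-validated RMSE curve for PLS1
#'
#' Seeded k-fold cross-validation over component counts `1..max_components`;
#' the chosen component count minimises RMSECV.
#'
#' @param X numeric matrix (n x p).
#' @param y numeric response.
#' @param max_components largest component count to score (capped at what the
#'   fold sizes allow).
#' @param folds number of CV folds (2 <= folds <= n).
#' @param seed integer seed for the fold assignment.
#' @return A list with `rmsecv` (vector over component counts), `best_ncomp`,
#'   and `model` (a `pls1` fitted on all rows with `best_ncomp`).
#' @export
pls_rmsecv <- function(X, y, max_components = 10, folds = 5, seed = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (folds < 2 || folds > n) stop("need 2 <= folds <= n")
  cap <- min(ncol(X), n - ceiling(n / folds) - 1)
  if (cap < 1) cap <- 1
  if (max_components > cap) max_components <- cap
  fold_id <- with_seed(seed, sample(rep(seq_len(folds), length.out = n)))
  press <- matrix(NA_real_, n, max_components)
  for (k in seq_len(folds)) {
    hold <- fold_id == k
    fit <- pls1_fit(X[!hold, , drop = FALSE], y[!hold], max_components)
    for (a in seq_len(max_components)) {
      pred <- predict(fit, X[hold, , drop = FALSE], ncomp = min(a, fit$ncomp))
      press[hold, a] <- (y[hold] - pred)^2
    }
  }
  rmsecv <- sqrt(colMeans(press))
  best <- which.min(rmsecv)
  list(rmsecv = rmsecv, best_ncomp = best,
       model = pls1_fit(X, y, best))
}
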