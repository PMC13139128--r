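#' @useDynLib nitrospec, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor cov dnorm lm mahalanobis pnorm prcomp predict qchisq
#'   qnorm rnorm runif sd var coef
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Derive a per-stage seed from the pipeline's global seed
#'
#' Each pipeline stage draws its own seed from the single global seed so that
#' changing, say, the model stage cannot perturb the simulated data. The
#' derivation is a small deterministic hash of the stage name folded into the
#' global seed, kept within the 32-bit integer range R requires of
#' `set.seed()`.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return An integer seed.
#' @export
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647L)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}
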