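predictor_fun <- function(model) {
  if (inherits(model, "model_bundle")) function(X) predict(model, X)
  else if (is.function(model)) model
  else stop("model must be a model_bundle or a prediction function")
}

#' Exact Shapley values by coalition enumeration
#'
#' For each sample, every coalition `S` of features is evaluated by predicting
#' with out-of-coalition features replaced by `baseline` values, and feature
#' `i` receives `phi_i = sum_S |S|! (p - |S| - 1)! / p! * (f(S + i) - f(S))`.
#' All `2^p` coalition predictions per sample are computed in one batched
#' model call and shared across features. Feasible for `p <= 16`.
#'
#' @param model a `model_bundle` or a function mapping a feature matrix to
#'   predictions.
#' @param X_explain numeric matrix of samples to explain (n x p).
#' @param baseline reference feature vector (length p), conventionally the
#'   training-set column means.
#' @return An object of class `shap_explanation`: `phi` (n x p, response
#'   units), `baseline_value` (`f` of the all-baseline input), `values`
#'   (feature values of the explained samples), `prediction` (unmasked model
#'   output per sample), and `method = "exact"`.
#' @export
shapley_exact <- function(model, X_explain, baseline) {
  f <- predictor_fun(model)
  X_explain <- as.matrix(X_explain)
  p <- ncol(X_explain)
  if (p > 16)
    stop("p = ", p, " > 16: exact enumeration infeasible, use shapley_sampled()")
  if (length(baseline) != p) stop("baseline length must equal ncol(X_explain)")
  n <- nrow(X_explain)

  n_mask <- 2^p
  masks <- matrix(FALSE, n_mask, p)
  for (i in seq_len(p)) masks[, i] <- bitwAnd(0:(n_mask - 1), 2^(i - 1)) > 0
  sizes <- rowSums(masks)
  # w(s) = s! (p - s - 1)! / p! = 1 / (p * choose(p - 1, s))
  wts <- 1 / (p * choose(p - 1, 0:(p - 1)))
  without <- lapply(seq_len(p), function(i) which(!masks[, i]))

  phi <- matrix(0, n, p)
  base_val <- NA_real_
  pred <- numeric(n)
  B <- matrix(baseline, n_mask, p, byrow = TRUE)
  for (s in seq_len(n)) {
    Xm <- B
    xs <- matrix(X_explain[s, ], n_mask, p, byrow = TRUE)
    Xm[masks] <- xs[masks]
    fv <- f(Xm)
    if (s == 1) base_val <- fv[1]
    pred[s] <- fv[n_mask]
    for (i in seq_len(p)) {
      idx0 <- without[[i]]
      gains <- fv[idx0 + 2^(i - 1)] - fv[idx0]
      phi[s, i] <- sum(wts[sizes[idx0] + 1] * gains)
    }
  }
  structure(
    list(phi = phi, baseline_value = base_val, values = X_explain,
         prediction = pred, baseline = as.numeric(baseline),
         method = "exact"),
    class = "shap_explanation"
  )
}

#' Sampled Shapley values by permutation averaging
#'
#' Monte-Carlo estimate of the same attribution as [shapley_exact()]: features
#' are inserted in `n_permutations` random orders and each feature's marginal
#' contribution is averaged, with a per-entry standard error from the spread
#' across permutations. Deterministic given `seed`.
#'
#' @inheritParams shapley_exact
#' @param n_permutations number of sampled feature orderings (default 2048).
#' @param seed integer seed.
#' @return A `shap_explanation` with `method = "sampled"` and an `se` matrix.
#' @export
shapley_sampled <- function(model, X_explain, baseline, n_permutations = 2048,
                            seed = NULL) {
  f <- predictor_fun(model)
  X_explain <- as.matrix(X_explain)
  p <- ncol(X_explain)
  if (length(baseline) != p) stop("baseline length must equal ncol(X_explain)")
  n <- nrow(X_explain)

  with_seed(seed, {
    sum_phi <- sumsq_phi <- matrix(0, n, p)
    base_row <- matrix(baseline, n, p, byrow = TRUE)
    base_val <- f(matrix(baseline, 1, p))[1]
    pred <- f(X_explain)
    for (b in seq_len(n_permutations)) {
      ord <- sample.int(p)
      # walk the order for all samples at once: p + 1 staged matrices
      cur <- base_row
      prev_val <- rep(base_val, n)
      for (step in seq_len(p)) {
        i <- ord[step]
        cur[, i] <- X_explain[, i]
        val <- f(cur)
        contrib <- val - prev_val
        sum_phi[, i] <- sum_phi[, i] + contrib
        sumsq_phi[, i] <- sumsq_phi[, i] + contrib^2
        prev_val <- val
      }
    }
    phi <- sum_phi / n_permutations
    se <- sqrt(pmax(sumsq_phi / n_permutations - phi^2, 0) / n_permutations)
    structure(
      list(phi = phi, baseline_value = base_val, values = X_explain,
           prediction = pred, baseline = as.numeric(baseline),
           se = se, n_permutations = n_permutations, method = "sampled"),
      class = "shap_explanation"
    )
  })
}

#' @export
print.shap_explanation <- function(x, ...) {
  cat(sprintf("<shap_explanation> %s: %d samples x %d features, baseline f = %.4f\n",
              x$method, nrow(x$phi), ncol(x$phi), x$baseline_value))
  invisible(x)
}

#' Rank features by mean absolute Shapley value
#'
#' @param expl a `shap_explanation`.
#' @param wavelengths optional nm labels of the features.
#' @return A data.frame sorted by decreasing `mean_abs_phi` (ties broken by
#'   feature order), with the per-feature correlation between feature value
#'   and Shapley value (`value_phi_cor`, the beeswarm sign association).
#' @export
shap_ranking <- function(expl, wavelengths = NULL) {
  p <- ncol(expl$phi)
  mean_abs <- colMeans(abs(expl$phi))
  assoc <- vapply(seq_len(p), function(i) {
    if (sd(expl$values[, i]) == 0 || sd(expl$phi[, i]) == 0) return(NA_real_)
    cor(expl$values[, i], expl$phi[, i])
  }, numeric(1))
  out <- data.frame(
    feature = seq_len(p),
    wavelength = if (!is.null(wavelengths)) wavelengths else NA_real_,
    mean_abs_phi = mean_abs,
    value_phi_cor = assoc
  )
  out[order(-out$mean_abs_phi, out$feature), ]
}

#' Long-format Shapley export for beeswarm plots
#'
#' @param expl a `shap_explanation`.
#' @param wavelengths optional nm labels.
#' @param sample_ids optional sample labels.
#' @return A data.frame with one row per (sample, feature): `sample`,
#'   `feature`, `wavelength`, `value`, `phi`.
#' @export
shap_long <- function(expl, wavelengths = NULL, sample_ids = NULL) {
  n <- nrow(expl$phi); p <- ncol(expl$phi)
  data.frame(
    sample = rep(sample_ids %||% seq_len(n), times = p),
    feature = rep(seq_len(p), each = n),
    wavelength = rep(if (!is.null(wavelengths)) wavelengths else NA_real_,
                     each = n),
    value = as.vector(expl$values),
    phi = as.vector(expl$phi)
  )
}
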