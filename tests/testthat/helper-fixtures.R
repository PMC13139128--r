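# small in-code fixtures shared across test files

# tiny spectra set with a known smooth shape plus seeded noise
tiny_spectra <- function(n = 6, wl = seq(500, 560, by = 2), noise = 0.005,
                         seed = 101) {
  set.seed(seed)
  base <- 0.3 + 0.1 * sin((wl - 500) / 12)
  refl <- t(replicate(n, base + rnorm(length(wl), 0, noise)))
  spectra_set(refl, wl)
}

# brute-force Savitzky-Golay oracle: explicit per-window least-squares polyfit
sg_oracle <- function(x, window, poly_order, deriv_order = 0) {
  m <- length(x)
  w <- (window - 1) / 2
  out <- numeric(m)
  for (t in seq_len(m)) {
    lo <- max(1, t - w); hi <- min(m, t + w)
    off <- (lo:hi) - t
    fit <- lm.fit(outer(off, 0:poly_order, `^`), x[lo:hi])
    out[t] <- fit$coefficients[deriv_order + 1] * factorial(deriv_order)
  }
  out
}

# modified Gram-Schmidt residual norms for a given selection chain
gram_schmidt_norms <- function(X, chain) {
  R <- X
  norms <- numeric(length(chain))
  for (s in seq_along(chain)) {
    v <- R[, chain[s]]
    norms[s] <- sqrt(sum(v^2))
    u <- v / norms[s]
    R <- R - u %o% as.numeric(crossprod(R, u))
  }
  norms
}

# brute-force SPXY oracle: recompute all pairwise joint distances each step
spxy_oracle <- function(X, y, n_train) {
  dx <- as.matrix(dist(X))
  dy <- abs(outer(y, y, `-`))
  d <- dx / max(dx) + dy / max(dy)
  upper <- which(upper.tri(d), arr.ind = TRUE)
  best <- upper[which.max(d[upper]), ]
  sel <- sort(as.integer(best))
  while (length(sel) < n_train) {
    rest <- setdiff(seq_len(nrow(X)), sel)
    mind <- sapply(rest, function(i) min(d[i, sel]))
    sel <- c(sel, rest[which.max(mind)])
  }
  sel
}

# factorial-orderings Shapley oracle: average marginal contribution over all
# p! insertion orders (feasible for p <= 6)
shapley_orderings_oracle <- function(f, x, baseline) {
  p <- length(x)
  perms <- permutations_all(p)
  phi <- numeric(p)
  for (r in seq_len(nrow(perms))) {
    cur <- baseline
    prev <- f(matrix(cur, 1))
    for (i in perms[r, ]) {
      cur[i] <- x[i]
      val <- f(matrix(cur, 1))
      phi[i] <- phi[i] + (val - prev)
      prev <- val
    }
  }
  phi / nrow(perms)
}

permutations_all <- function(p) {
  if (p == 1) return(matrix(1))
  sub <- permutations_all(p - 1)
  out <- matrix(0L, 0, p)
  for (i in seq_len(p)) {
    rest <- setdiff(seq_len(p), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# planted-band regression problem for CARS recovery checks: smooth spectra-like
# noise plus 5 informative bands
planted_bands_data <- function(n = 80, p = 500, centers = c(60, 150, 250, 340, 430),
                               noise = 0.3, seed = 1) {
  set.seed(seed)
  raw <- matrix(rnorm(n * (p + 10)), n)
  X <- sapply(seq_len(p), function(j) rowMeans(raw[, j:(j + 10)])) # band-correlated
  latent <- rnorm(n)
  for (ct in centers) {
    prof <- exp(-((seq_len(p) - ct)^2) / (2 * 3^2))
    X <- X + latent %o% prof
  }
  y <- latent + rnorm(n, 0, noise)
  list(X = X, y = y, centers = centers)
}
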