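test_that("SG smoothing preserves constants and fitted-class polynomials", {
  wl <- 400:460
  const <- spectra_set(matrix(0.42, 2, length(wl)), wl)
  expect_equal(sg_smooth(const, 15, 2)$reflectance, const$reflectance,
               tolerance = 1e-12)

  quad <- outer(c(1, 2), wl, function(a, l) a * 1e-5 * l^2 - 0.008 * l + 2)
  sm <- sg_smooth(spectra_set(quad, wl), 15, 2)
  expect_lt(max(abs(sm$reflectance - quad)), 1e-9)

  expect_error(sg_smooth(tiny_spectra(wl = seq(500, 520, 2)), 15, 2),
               "wider than spectrum")
  expect_error(sg_smooth(tiny_spectra(), 14, 2), "odd")
})

test_that("SG equals the brute-force per-window polyfit oracle on a noisy sine", {
  set.seed(5)
  wl <- seq(1000, 1200, by = 1)
  x <- sin(wl / 15) + rnorm(length(wl), 0, 0.2)
  sm <- sg_smooth(spectra_set(rbind(x), wl), 15, 2)
  expect_lt(max(abs(sm$reflectance[1, ] - sg_oracle(x, 15, 2, 0))), 1e-9)
  d2 <- second_derivative(spectra_set(rbind(x), wl), 15, 2)
  expect_lt(max(abs(d2$reflectance[1, ] - sg_oracle(x, 15, 2, 2))), 1e-9)

  # second opinion at interior points from an established filter implementation
  # (edge policies differ by design: truncated re-fit here)
  ref <- signal::sgolayfilt(x, p = 2, n = 15)
  interior <- 8:(length(x) - 7)
  expect_lt(max(abs(sm$reflectance[1, interior] - ref[interior])), 1e-9)
})

test_that("second derivative is exact on polynomials and scales with spacing", {
  wl <- seq(400, 520, by = 2) # 2 nm grid: checks the 1/(step^2) scaling
  lin <- spectra_set(outer(c(1, -1), wl, function(a, l) a * (0.001 * l + 0.1)), wl)
  d2 <- second_derivative(lin, 15, 2)
  w <- 7
  interior <- (w + 1):(length(wl) - w)
  expect_lt(max(abs(d2$reflectance[, interior])), 1e-9)

  cub <- spectra_set(rbind(1e-8 * wl^3 - 2e-5 * wl^2 + 0.01 * wl), wl)
  d2c <- second_derivative(cub, 15, 3)
  expect_lt(max(abs(d2c$reflectance[1, interior] -
                      (6e-8 * wl[interior] - 4e-5))), 1e-6)

  irregular <- spectra_set(matrix(1:40 / 40, 2, 20), c(1:19, 25))
  expect_error(second_derivative(irregular, 7, 2), "non-uniform")
})

test_that("chained SG then SD matches the direct second-derivative kernel on smooth input", {
  wl <- seq(600, 800, by = 1)
  cub <- rbind(1e-8 * wl^3 - 1e-5 * wl^2 + 0.002 * wl)
  x <- spectra_set(cub, wl)
  chained <- sg_second_derivative(x, 15, 3)
  direct <- second_derivative(x, 15, 3)
  w <- 7
  interior <- (w + 1):(length(wl) - w)
  expect_lt(max(abs(chained$reflectance[, interior] -
                      direct$reflectance[, interior])), 1e-6)
})

test_that("MSC inverts affine scatter and is idempotent for a fixed reference", {
  x <- tiny_spectra(n = 5, noise = 0)
  ref <- colMeans(x$reflectance)
  scattered <- sweep(x$reflectance * 1.7, 2, rep(0.05, ncol(x$reflectance)), "+")
  res <- msc(spectra_set(scattered, x$wavelengths), reference = ref)
  expect_lt(max(abs(res$spectra$reflectance -
                      matrix(ref, 5, length(ref), byrow = TRUE))), 1e-9)

  # identity when the sample equals the reference
  same <- msc(spectra_set(rbind(ref, ref + 0.01 * sin(seq_along(ref))),
                          x$wavelengths), reference = ref)
  expect_equal(same$spectra$reflectance[1, ], ref, ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(same$model$coefficients$slope[1], 1, tolerance = 1e-12)
  expect_equal(same$model$coefficients$offset[1], 0, tolerance = 1e-12)

  once <- msc(x, reference = ref)$spectra
  twice <- msc(once, reference = ref)$spectra
  expect_equal(once$reflectance, twice$reflectance, tolerance = 1e-10)

  flat <- spectra_set(matrix(0.5, 2, 31), x$wavelengths)
  expect_error(msc(flat, reference = ref), "slope is zero.*s0001")
})

test_that("MSC-corrected scatter-perturbed spectra correlate with the reference", {
  # one clean leaf spectrum under twenty random affine scatter perturbations
  # plus detector noise: MSC must recover near-perfect agreement
  cfg <- generator_config("NSS", scatter_slope_sd = 0, scatter_offset_sd = 0,
                          noise_sd_core = 0, noise_sd_edge = 0, seed = 8)
  clean <- generate_spectra(c(2.4, 2.5), cfg)$spectra$reflectance[1, ]
  set.seed(2)
  scattered <- t(replicate(20, clean * rnorm(1, 1, 0.1) + rnorm(1, 0, 0.02) +
                             rnorm(length(clean), 0, 0.002)))
  res <- msc(spectra_set(scattered, cfg$wavelengths), reference = clean)
  cors <- apply(res$spectra$reflectance, 1, cor, y = res$model$reference)
  expect_true(all(cors >= 0.999))
})

test_that("SNV normalises rows, is idempotent, and ignores per-sample affine maps", {
  s <- snv(spectra_set(matrix(c(1, 2, 3), 1), c(500, 600, 700)))
  expect_equal(s$reflectance[1, ], c(-1, 0, 1), ignore_attr = TRUE)

  x <- tiny_spectra()
  out <- snv(x)$reflectance
  expect_lt(max(abs(rowMeans(out))), 1e-12)
  expect_lt(max(abs(apply(out, 1, sd) - 1)), 1e-12)
  expect_equal(snv(snv(x))$reflectance, out, tolerance = 1e-12)

  affine <- spectra_set(x$reflectance * 3.2 + 0.7, x$wavelengths)
  expect_equal(snv(affine)$reflectance, out, tolerance = 1e-10)

  flat <- spectra_set(matrix(2, 1, 5), seq(500, 540, 10))
  expect_error(snv(flat), "constant spectrum.*s0001")
})

test_that("per-wavelength Pearson screening matches hand values", {
  wl <- c(500, 510, 520)
  y <- c(2, 4, 5, 4, 5)
  X <- cbind(y, -y, c(1, 2, 3, 4, 5))
  r <- pearson_by_wavelength(spectra_set(X, wl), y)
  expect_equal(unname(r[1]), 1)
  expect_equal(unname(r[2]), -1)
  expect_equal(unname(r[3]), 0.7746, tolerance = 1e-3) # hand Pearson

  Xz <- cbind(y, rep(1, 5))
  expect_warning(rz <- pearson_by_wavelength(spectra_set(Xz, wl[1:2]), y),
                 "zero-variance")
  expect_equal(unname(rz[2]), 0)
})
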