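---
title: "Hyperspectral inversion of leaf nitrogen: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hyperspectral inversion of leaf nitrogen: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Leaf nitrogen content (% of dry mass) is the standard nutritional readout for
orchard management, conventionally measured by Kjeldahl wet chemistry —
destructive, slow, and unsuited to monitoring. Contiguous 400–2500 nm leaf
reflectance carries the same information indirectly: chlorophyll absorbs in
the visible (430/460/680 nm), proteins and other nitrogen-bearing compounds
absorb near 2045 and 2180 nm, structural carbohydrates (whose share falls as
nitrogen rises) near 2340/2385 nm, and leaf water dominates at
970/1200/1450/1940 nm. `nitrospec` implements a full inversion pipeline from
such spectra to nitrogen: preprocessing, wavelength selection, sample
partitioning, four regression models, evaluation, cross-stage validation, and
Shapley attribution — plus a calibrated synthetic generator that stands in
for field data, so every step of the procedure is testable end to end.

# The synthetic generator

`generate_spectra()` builds each spectrum as

```
r(lambda) = clip( a_s * [ continuum(lambda) * exp(-sum_k d_k * G(lambda; mu_k, sigma_k)) ]
                  + b_s + eps(lambda), 0.001, 0.999 )
```

* `continuum` is a low visible shelf rising through a logistic red edge near
  705 nm to a near-infrared plateau (~0.5), with a gentle decline into the
  short-wave infrared;
* `G` are Gaussian absorption profiles at the pigment, water, protein, and
  structural-carbohydrate centres listed in `absorption_features_default()`;
* the optical depths `d_k` are linear in four per-sample biochemical latents
  whose correlations with nitrogen are configuration, not code: chlorophyll
  +0.9, protein +0.9, water +0.3, structural carbohydrates −0.7. Pigment and
  protein absorption therefore deepens with nitrogen (reflectance falls),
  structural absorption shallows — which is what makes NIR/SWIR reflectance
  negatively correlated with nitrogen;
* `(a_s, b_s)` are per-sample multiplicative/additive scatter perturbations
  (sd 0.04 and 0.01) of the kind MSC and SNV exist to remove;
* `eps` is Gaussian noise with sd 0.002 in the grid core, inflated to 0.008
  over the outer 200 nm, mimicking detector-edge noise.

Nitrogen itself is drawn from a normal distribution truncated to the observed
range of each phenological stage: new-shoot-stop (NSS; n = 125, mean
2.479 % N, sd 0.201, range 2.035–2.873) or autumn-shoot-stop (ASS; n = 118,
mean 2.795, sd 0.248, range 2.235–3.752). The ASS configuration additionally
adds +0.03 to the structural-band base depths, so cross-stage validation sees
a genuine covariate shift, not merely new noise.

What the generator does **not** emulate: radiative-transfer physics
(PROSPECT-class leaf optics), instrument artifacts (detector splices, dark
current), within-leaf spatial variation, and the long-tailed residual
structure of real field campaigns. Tests passing on this generator
demonstrate that the *procedure* is implemented correctly and recovers known
structure; they do not certify field performance.

One calibration note: absorption-feature depths and latent loadings were
fixed once so that the full pipeline's synthetic test-set R² lands in the
0.6–0.8 regime reported for real apple-leaf data — i.e. the synthetic task is
neither trivially easy nor hopeless. The marginal wavelength–nitrogen
correlations this produces (|r| up to ~0.77 in the SWIR) are stronger and
more linear than the real data's (< 0.3 after preprocessing), which has a
visible consequence discussed under "Model comparison" below.

# Preprocessing

Savitzky–Golay smoothing fits a polynomial of order 2 over a 15-point moving
window by least squares and keeps the fitted central value; the second
derivative keeps the fitted curvature scaled by 1/(step)², in units of
reflectance per nm². Window and order have no single field standard;
15/2 is common ASD-leaf practice at 1 nm sampling and is configurable
everywhere. Boundary points are re-fitted on truncated windows rather than
obtained from reflection padding, so no fabricated values enter the band
edges. MSC regresses each spectrum on a reference (by default the mean of
the fitting partition — training rows only inside modelling, to avoid
leakage) and inverts the fitted affine scatter; SNV centres and scales each
row by its own statistics (n − 1 denominator). The default modelling chain
is SG → second derivative, which, on both the real data and the generator,
yields the strongest per-wavelength Pearson correlations with nitrogen.

# Outlier screening and partitioning

Mahalanobis screening operates in PCA score space (components covering 95 %
of variance, capped at 10 — with 125 samples on 2101 bands the full-rank
covariance is singular, so a score-space distance is the standard recourse)
and flags samples beyond the chi-square 0.975 quantile, one pass. SPXY
partitioning normalises Euclidean spectral distance and absolute nitrogen
distance by their maxima, sums them, and applies Kennard–Stone max–min
selection; 125 samples at a 0.6 training fraction give the 75/50 split.
Ties are broken by lowest sample index so the split is bit-reproducible.

# Wavelength selection

CARS runs 50 Monte-Carlo iterations; each fits PLS1 on a random 80 % of the
training rows over the currently retained bands, ranks bands by normalised
absolute regression coefficients, enforces the exponentially decreasing
retention schedule (all bands survive run 1, exactly 2 survive run 50), and
applies adaptive reweighted sampling. The PLS component count is chosen once
by 5-fold RMSECV (cap 10) before the loop and capped by the retained-set
size within it. The winning run minimises 5-fold RMSECV. SPA then builds
successive-projection chains from every CARS-winner band and scores each
(start, length) prefix — by 5-fold CV on the training rows by default, or on
a supplied held-out set (a protocol seen in parts of the application
literature; available as `validation = "holdout"` and via `published_protocol` in
the pipeline).
Selection defaults to training rows only; the published 15-band set
(411 … 2394 nm) ships as `reference_wavelengths()` for building models
without re-running selection.

# Models

All four regressors share the fit/predict contract of `model_bundle` and see
the selected bands **sorted into spectral order** — convolution windows
assume local structure, and selection order would scramble it.

* **RF**: 300 trees, depth ≤ 8, ≥ 3 samples per leaf (via `ranger`, seeded,
  single-threaded).
* **SVM**: RBF kernel, features standardised by training statistics,
  `(C, gamma)` from seeded 5-fold CV over `2^(-5..9) x 2^(-15..1)`,
  epsilon 0.01.
* **CNN**: Conv(8 kernels, 3 taps, same padding) → ReLU → MaxPool(2/2) →
  Conv(8, 3) → ReLU → MaxPool(2/2) → Dropout(0.5) → FC(32) → ReLU →
  Linear(1); loss MSE + 0.001·Σw²; Adam at 0.001 with ×0.1 plateau decay;
  ≤ 500 epochs; early stopping on an internal 20 % validation fold with the
  best-epoch weights restored. Implemented in compiled code (RcppArmadillo)
  with all randomness drawn from R's RNG, so results reproduce under
  `set.seed()` and the whole swarm search below stays affordable on one CPU.
  Unstated training controls were set as follows: fully connected width 32;
  plateau patience 40 epochs and stopping patience 150 — with patience ~20
  the learning rate collapses after the first noisy plateau of the small
  validation fold and the 500-epoch budget is wasted (measured: test R²
  roughly halves).
* **PSO-CNN**: global-best PSO (20 particles, 15 iterations, inertia 0.729,
  c1 = c2 = 1.49445, velocity clamp 0.5·range, reflecting bounds) over
  learning rate 0.0005–0.01 (log10), batch size 16–512 (log2, rounded and
  clamped to the training size), and L2 coefficient 0.0001–0.1 (log10), with
  the architecture frozen. Fitness is the RMSE of a freshly trained CNN on a
  25 % inner validation fold carved from the training rows (never the test
  set, unless `published_protocol` deliberately reproduces the published protocol).

Three PSO choices deserve justification because measurement forced them.
First, every fitness evaluation trains with the *same* derived seed (common
random numbers), so particles are compared under paired noise; with
per-evaluation seeds the fold noise dominated the hyperparameter signal and
the search could return worse settings than its own starting point (the
per-evaluation policy remains available). Second, one particle is
warm-started at the baseline CNN configuration, making the searched optimum
at least as good as the baseline on the fitness fold by construction.
Third, the returned model is the best particle's actual model rather than a
fresh-seed refit at the chosen hyperparameters: with 75 training rows a
refit under a new initialisation routinely lands far from the fitness the
search measured (observed on one diagnostic seed: refit test R² −0.21
vs 0.51 for the measured model). The refit behaviour is available as
`final_fit = "retrain"`.

# Evaluation

`compute_metrics()` reports R² (1 − SSE/SST), RMSE (population denominator,
as the evaluation formulas print it), and two RPD variants: `rpd_printed`
uses predicted deviations in the numerator — the form printed in the source
formulas — and `rpd_conventional` is sd(observed)/RMSE, the standard
chemometric definition. The two coincide for perfect predictions and are
both reported because the printed form is unusual and readers will expect
the conventional one (< 1.4 poor, 1.4–2.0 moderate, > 2.0 strong).
`residual_diagnostics()` reports the share of residuals within one sd of
their mean (boundary inclusive, n − 1 sd — about 68.3 % under normality), a
20-bin histogram with fitted-normal ordinates, and Q–Q pairs at Blom
plotting positions. `cross_stage_validate()` scores a fitted model on the
other phenological stage and adds the OLS slope of predicted on observed.

# Attribution

`shapley_exact()` enumerates all 2^p coalitions (p ≤ 16; at the default 15
bands that is 32,768 batched model calls per sample), replacing
out-of-coalition features by a single reference vector — the training-set
column means. This baseline-replacement semantics is a stated limitation:
it is single-reference SHAP, not marginal integration over the data
distribution. `shapley_sampled()` is the permutation estimator for larger p,
with per-entry standard errors. Exact efficiency, symmetry, and dummy axioms
are enforced by tests. On reflectance features at protein/water bands the
value–attribution correlation is negative — higher reflectance means
shallower absorption, hence less nitrogen; note that on second-derivative
features this sign flips at absorption centres (curvature rises with depth),
so beeswarm signs must be read against the feature space the model was fed.

# Pipeline, problem sizes, and model comparison

`run_pipeline()` chains simulate → preprocess → outlier screening → SPXY →
CARS-SPA → four models → evaluation → cross-stage validation → attribution,
with one global seed fanned out per stage (`stage_seed()`), a stage manifest
with timings and artifact hashes, and `published_protocol` switching selection
scoring and PSO fitness to the published (test-set) protocol. Default
problem sizes are the study's own: 125 NSS + 118 ASS samples on the
2101-band grid, 50 CARS runs, ≤ 15 selected bands, 20 × 15 swarm
evaluations; one full run takes a couple of minutes on a single CPU, and
package tests run the 5-seed battery at exactly these sizes.

On synthetic seed batteries the PSO-CNN improves on the baseline CNN in
every seed, but the published ranking SVM ≤ RF ≤ CNN ≤ PSO-CNN is **not**
generally reproduced: the random forest and the SVM come out on top. The
generator's latent model is linear-Gaussian, so its band–nitrogen signal is
smoother and more linear than the real data's (whose post-preprocessing
correlations stay below 0.3), and kernel/ensemble methods exploit that
structure at n = 75 as well as or better than a small convolutional network;
on seeds where selection admits noisy detector-edge bands the CNN overfits
them where the forest's bagging shrugs them off. This is reported as
measured — a property of the synthetic conditions, not of the
implementations — and the corresponding performance-regime test in the
acceptance suite fails on the ordering for exactly this reason.

# Known limitations

* The generator omits radiative-transfer realism and instrument artifacts;
  absolute performance numbers on it do not transfer to field data.
* Exact Shapley is limited to p ≤ 16; the sampling estimator's error is
  reported but grows for strongly interacting models.
* CNN reproducibility is guaranteed under single-threaded execution with a
  fixed seed; BLAS-threaded environments may reorder floating-point sums.
* Outlier screening is single-pass by design; iterative re-screening would
  change flagged sets near the threshold.
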