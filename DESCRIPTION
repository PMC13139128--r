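Package: nitrospec
Title: Hyperspectral Inversion of Leaf Nitrogen Content
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible chemometrics pipeline for estimating leaf nitrogen
    content (% dry mass) from 400-2500 nm reflectance spectra. Provides a
    calibrated synthetic generator for ASD FieldSpec-style apple-leaf spectra,
    Savitzky-Golay smoothing and second-derivative transforms, multiplicative
    scatter correction and standard normal variate normalisation, Mahalanobis
    outlier screening, SPXY (joint X-Y distance) sample partitioning, hybrid
    CARS-SPA characteristic wavelength selection over a PLS1 core, four
    regression models (random forest, RBF support vector regression, a compact
    one-dimensional convolutional network, and its particle-swarm-tuned
    variant), R2/RMSE/RPD evaluation with residual diagnostics, cross-stage
    validation, and exact or permutation-sampled Shapley attribution of the
    selected wavelengths.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    ranger,
    e1071,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    signal,
    rpart
Config/testthat/edition: 3
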