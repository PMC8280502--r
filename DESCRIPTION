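Package: lstar
Title: Latent State-Trait Models with Autoregressive Effects for
    Single- and Multi-Rater Panel Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimation and simulation of latent state-trait models with
    autoregressive effects (LST-AR) and their multi-rater extension
    (MR-LST-AR), a CT-C(M-1) multitrait-multimethod structure for dyadic
    longitudinal panel data.  Builds model-implied moment structures in
    closed form, fits them by full-information maximum likelihood under
    arbitrary missing-data patterns, reports chi-square, CFI and RMSEA fit
    indices, nonparametric bootstrap confidence intervals, and the complete
    system of variance-decomposition coefficients (reliability, occasion
    specificity, time consistency, predictability by the first-occasion
    trait, latent retest correlations, and rater-consistency coefficients).
    A synthetic-data generator produces dyadic panels with study-like wave
    nonparticipation for simulation studies and parameter recovery checks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
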