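Package: twowave
Title: Separating Cross-Sectional from Longitudinal Genetic Effects in Two-Wave Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying genetic effects on age-related decline with
    two-wave (baseline and follow-up) cohort data. Provides a generative
    simulator for a structural causal model in which time-invariant genetic
    effects, time-varying environments and gene-by-environment (gene-by-age)
    interactions jointly produce phenotypes measured with error; the three
    standard two-wave change definitions (absolute difference, baseline-
    adjusted residual change, log-difference) with age and follow-up-duration
    residualization and composite-score construction; per-variant association
    scans with covariate adjustment, gene-by-sex interactions and inverse
    probability weighting for selective follow-up participation; summary-
    statistic standardization and a two-sample Mendelian randomization stage
    (inverse-variance weighted estimator, Cochran Q, MR-Egger intercept,
    instrument strength); and an evaluation harness that quantifies estimator
    bias, calibration and power against a closed-form oracle for the bias of
    baseline-adjusted change scores.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    sandwich,
    lmtest,
    jsonlite
Config/testthat/edition: 3
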