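Package: metGP
Title: Reaction-Norm Kernel Models for Multi-Environment Genomic Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for genomic prediction in multi-environment plant
    breeding trials. Builds genomic (marker), pedigree and environmental-
    covariable relationship kernels and their Hadamard-product interaction
    structures, fits multi-kernel variance-component models by Bayesian
    Gibbs sampling in the eigenbasis of each kernel, performs stage-one
    phenotypic analysis (per-site mixed models, broad-sense heritability,
    a factor-analytic model of between-site genetic covariance with biplot
    coordinates), and evaluates prediction accuracy under four schemes:
    random line-level (CV1) and plot-level (CV2) cross-validation,
    pairwise-site prediction and leave-one-site-out prediction of entirely
    untested environments.  A synthetic multi-environment-trial generator
    with partially replicated (p-rep) augmented designs and known ground
    truth supports calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Rcpp,
    lme4
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
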