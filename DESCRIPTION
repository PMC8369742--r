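Package: gaprog
Title: Box-Cox Mixed-Effects Modelling of Geographic Atrophy Progression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models longitudinal geographic-atrophy (GA) lesion-size
    trajectories with a disease-age-parameterized linear mixed-effects model
    on a Box-Cox-transformed scale.  Provides the constrained model fit via an
    iterative working-covariable algorithm, AIC-based selection of the
    transformation parameter with Jacobian correction on the original scale,
    per-eye age-of-onset back-projection, bias-corrected (smearing) prediction
    of lesion size in square millimetres, patient-cluster bootstrap confidence
    intervals, and a synthetic cohort generator for simulation studies.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    lme4,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
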