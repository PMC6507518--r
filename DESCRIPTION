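Package: aiptw
Title: Augmented Inverse Probability of Treatment Weighting for
    Two-Level Random Coefficient Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates average causal effects from clustered observational
    data with a two-level Gaussian random coefficient model when some
    clusters contain only treated or only control units (practical
    positivity violation). Provides inverse-probability-of-treatment
    weighted (IPTW) estimation on the original and trimmed samples,
    augmented IPTW (AIPTW) estimators that add one predicted missing-arm
    pseudo-observation per violating cluster using cluster-average
    treatment corrected (SATC/RSATC) outcome models, a nonparametric
    AIPTW contrast, robust cluster sandwich and cluster-bootstrap
    standard errors, and a calibrated Monte Carlo engine (latent-index
    treatment assignment with analytic moment calibration) for
    evaluating bias, standard errors and coverage of the estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
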