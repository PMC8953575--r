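Package: bacara
Title: Bayesian Covariate-Adjusted Response-Adaptive Group Sequential Trial Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation toolkit for two-arm group sequential clinical trials
    with personalized (covariate-adjusted) response-adaptive randomization on a
    binary endpoint. Patients carry binary covariates, outcomes follow a probit
    regression model, and posterior inference uses Albert-Chib truncated-normal
    data augmentation with a maximum-likelihood-centered normal prior.
    Implements fixed 1:1 randomization, Rosenberger-style response-adaptive
    randomization, two personalized allocation rules driven by the posterior
    probability of individual treatment benefit, and a Bayesian design (BaCARA)
    that monitors a subgroup-averaged treatment-effect statistic with
    calibrated superiority and futility cutoffs. Includes the conventional
    O'Brien-Fleming alpha-spending group sequential test for comparator
    designs, an operating-characteristics engine over replicated trials, and
    simulation-based calibration of the monitoring cutoffs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE, load = "source")
RoxygenNote: 7.3.3
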