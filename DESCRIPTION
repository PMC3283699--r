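Package: ebpi
Title: Empirical-Bayes Prediction Intervals for Panels of Log Odds Ratios
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Shrinkage-based interval estimation for panels of exchangeable
    log odds ratios. Estimates a common prior (mean and variance) from the
    panel itself by the method of moments, with an optional correction for
    correlated estimates, and constructs empirical-Bayes prediction
    intervals that are shorter than the usual Wald confidence intervals
    while retaining nominal average coverage. Includes the effect-estimation
    front end for case-control data (2x2 tables, per-variant logistic
    regression, minor-allele-frequency and Hardy-Weinberg filters, and
    linkage-disequilibrium-based covariance approximation), a coverage
    simulation framework, a synthetic genotype fixture generator, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    Matrix,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
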