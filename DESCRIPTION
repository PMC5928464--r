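Package: seqcausal
Title: Sequential Conditional Mean Models and Marginal Structural Models
    for Time-Varying Exposures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of total causal effects of a time-varying exposure on
    repeated outcome measures in the presence of time-dependent confounding.
    Fits sequential conditional mean models (SCMMs) by generalized estimating
    equations with independence or unstructured working correlation and
    cluster-robust sandwich variances, optionally adjusting for a pooled
    propensity score (doubly robust in linear models). Also fits marginal
    structural models by inverse-probability-of-treatment weighting with
    unstabilized, stabilized and percentile-truncated weights, and provides a
    cluster-bootstrap test for long-term direct effects of past exposures on
    later outcomes not mediated through intermediate exposures. Includes a
    synthetic longitudinal data generator with exposure-outcome feedback and
    subject-level random effects, and a simulation harness comparing the
    estimators by bias and empirical precision.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    pracma,
    optparse
Config/testthat/edition: 3
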