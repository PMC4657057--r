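Package: fpboot
Title: Fingerprint Resampling for Fast Likelihood Bootstraps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Accelerates bootstrap-type resampling of likelihood-based
    estimators. Each resampled data set is summarized into a derivative-based
    fingerprint (finite-difference gradient and, optionally, Hessian of its
    log-likelihood at the original optimum). The fingerprint-to-optimum
    relation is learned from already-solved resamples with least-squares
    support vector machine (kernel ridge) regression, and predictions serve
    either as warm starts for a Nelder-Mead optimizer or as direct
    substitutes for optimization. Ships four objective models (exponential,
    no-intercept regression, profiled linear mixed model, nonstationary GEV),
    synthetic-data generators, exact function-evaluation accounting, and an
    evaluation layer for percentile-bootstrap speed-accuracy trade-offs
    including parallel-batch replay.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
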