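Package: acce
Title: Amplified Confounding-Based Estimation of Residual Confounding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates total residual confounding (including unmeasured
    confounding) of a nonrandomized treatment effect by deliberately
    amplifying it. Two nested linear-probability propensity-score models are
    fitted that differ only in an Introduced Variable strongly predictive of
    exposure; residual confounding is back-extrapolated from the change in
    the stratified treatment effect estimate between the models, using the
    proportionality of bias amplification to 1/(1 - R-squared) and a
    Bross-equation adjustment for any Introduced Variable-outcome
    association. Provides a calculator for pre-computed summary inputs, a
    qualitative probe classification, a synthetic-cohort simulator for
    validation experiments, and case-resampling bootstrap confidence
    intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
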