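Package: valsize
Title: Sample Size Assessment for External Validation of Survival
    Prognostic Models
Version: 0.1.0
Authors@R:
    person("Val", "Size", email = "maintainer@valsize.org", role = c("aut", "cre"))
Description: Tools for studying how many outcome events an external
    validation of a time-to-event prognostic model needs. Implements six
    validation performance measures (Harrell's c-index, the Royston-Sauerbrei
    D statistic and its explained-variation transform R2_D, the O'Quigley
    explained randomness rho2_OXS, the inverse-probability-of-censoring
    weighted Brier score, and the calibration slope) together with standard
    errors; a fixed-event-count stratified resampling engine; a Monte-Carlo
    evaluation layer (percent bias, standardized bias, RMSE, coverage,
    confidence-interval width, tolerance-band proportions); and a synthetic
    cohort generator that emulates a large primary-care registry with a low
    event fraction and controllable miscalibration of the validated model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    splines,
    stats,
    survival,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
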