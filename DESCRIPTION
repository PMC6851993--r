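Package: progrel
Title: Within-Subject Reliability of Longitudinal Rating Scales via
    State Space Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Separates true long-term disease progression from measurement
    error in repeated clinical rating-scale scores.  Fits a linear Gaussian
    state space model (a local level model with population drift) to
    longitudinal cohorts by pooled maximum likelihood, with exact handling
    of missing monthly observations via the Kalman filter.  Provides the
    within-subject reliability of 1-year change scores, patient-level
    percentile bootstrap confidence intervals, paired washout-threshold
    comparisons for motor assessments, principal-component factor subscores
    with varimax rotation, model diagnostics, and a synthetic cohort
    generator emulating the visit structure of de novo Parkinson's disease
    studies such as PPMI.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
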