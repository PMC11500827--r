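Package: wristqome
Title: Quality-of-Movement-Experience Metrics from Wrist-Worn IMU Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify the statistical quality of the daily arm
    movement experience of stroke survivors from a wrist-worn inertial
    measurement unit (IMU). Implements Madgwick-filter gravity removal, a
    two-threshold arm-inactivity filter, forearm tilt-angle estimation with
    respect to gravity, distributional movement features (binned magnitude
    distributions, speed ratios, tilt-distribution moments), Sample Entropy
    complexity measures with per-signal parameter defaults and grid search,
    and cohort-level statistics relating features to upper-extremity
    impairment (regression, ANOVA, Cohen's D, variance inflation factors,
    and AIC-guided backward elimination). A synthetic cohort generator with
    impairment-dependent activity, posture and complexity gradients makes
    the full pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    Rcpp,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
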