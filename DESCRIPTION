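Package: wtraj
Title: Trajectory-Class Prediction of Long-Term Weight Change from
    Self-Reported Weight Logs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Defines weight-change outcome classes from longitudinal
    self-reported weight data by dynamic time warping (DTW) consensus
    clustering refined with DTW k-means, trains per-time-frame classifiers
    and regressors on percent weight-change trajectories, and predicts
    three- or five-class nine-month weight-change outcomes for partially
    observed individuals. Implements the supporting rules end to end:
    participant exclusion screening, linear interpolation of irregular
    weight logs, slope extrapolation to the prediction time frame,
    eligibility checks, cutoff-based conversion of regression output to
    classes, evaluation with per-class metrics and a random-prediction
    baseline, and a synthetic cohort generator with known trajectory
    archetypes for fully reproducible end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    graphics,
    jsonlite,
    nnet,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
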