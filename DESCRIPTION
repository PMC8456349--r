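Package: hdevents
Title: Prediction of Intradialytic Adverse Events from Hemodialysis Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for predicting adverse events during
    hemodialysis (HD) sessions from irregularly sampled dialysis-machine and
    staff-recorded physiological time series. Implements session cleaning
    with last-observation-carried-forward semantics, an 84-feature linear and
    differential extraction engine, outcome labeling with event-group
    schemes and a label-permutation negative control, a from-scratch
    two-class averaged perceptron, random-undersampling boosted trees,
    greedy forward feature-combination selection, cross-validated ROC/AUC
    evaluation with session- or patient-level partitioning, and
    cutoff-timing and session-truncation experiments. Ships a synthetic
    HD-cohort generator with a known event-generating mechanism so every
    stage is testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    rpart,
    e1071,
    randomForest,
    jsonlite
Suggests:
    yaml,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
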