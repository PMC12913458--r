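Package: microstatr
Title: EEG Microstate Segmentation and Multi-Domain Biomarker Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments multichannel resting-state EEG into quasi-stable
    microstates by K-means clustering of global-field-power peak
    topographies with per-sample back-fitting, extracts an 80-feature
    multi-domain vector per subject (temporal dynamics, state-conditioned
    Welch band power, symbolic-sequence complexity, higher-order
    transition and graph metrics), screens features between groups with
    nonparametric tests and effect sizes, and evaluates interpretable
    classifiers with Shapley-value feature ranking. Ships a synthetic
    semi-Markov EEG generator with plantable group effects so the whole
    pipeline is testable without any external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    igraph,
    jsonlite,
    glmnet,
    randomForest,
    e1071,
    nnet,
    xgboost,
    pROC,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
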