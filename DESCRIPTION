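Package: fingertap
Title: Video-Based Quantification of Finger-Tapping Motor Characteristics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies Parkinson's disease motor characteristics from
    hand-keypoint time series of the MDS-UPDRS finger-tapping test. Builds a
    palm-scaled thumb-index distance signal from per-frame hand keypoints,
    segments tapping cycles by peak detection, and extracts 14 interpretable
    features covering hypokinesia (amplitude), bradykinesia (cycle duration),
    combined speed measures, the sequence effect (linear trends across cycles)
    and hesitation-halts (coefficients of variation and interruption counts).
    Includes principal component analysis with varimax rotation of the feature
    matrix, multi-class and ordinal (cumulative binary decomposition) severity
    classification with leave-one-subject-out cross-validation, the associated
    evaluation metrics, and a synthetic tapping simulator with known
    ground-truth deficit parameters for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    nnet,
    randomForest,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
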