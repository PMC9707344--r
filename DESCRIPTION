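Package: neurokin
Title: Kinematic Feature Extraction and Abnormality Detection for
    Vision-Based Neurological Screening Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify performance on four vision-based neurological
    screening tests (finger tapping, finger-to-finger, forearm roll, and
    stand-up-and-walk) from 2D/3D human pose time series. Provides readers for
    per-frame keypoint JSON and a flat tabular pose format, pose pre-processing
    (truncation, reference-length normalization, median and Savitzky-Golay
    smoothing), cycle and extrema detection, clinically interpretable kinematic
    and spatio-temporal features (amplitude, period, frequency, left-right
    asymmetry, path smoothness, velocity-angle symmetry, gait segmentation,
    step length, width and time, cadence, knee-angle symmetry), a normal-versus-
    abnormal classification harness with video- and subject-wise cross
    validation, and a seeded synthetic pose simulator with ground-truth motion
    parameters for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    zoo,
    jsonlite,
    yaml,
    data.table,
    randomForest,
    e1071,
    xgboost,
    glmnet,
    nnet,
    pROC
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
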