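Package: fmdetect
Title: Lightweight Fetal Movement Detection from Wearable IMU Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for detecting fetal movement from six-axis
    inertial measurement unit (IMU) recordings captured by an abdominal
    wearable. Provides a synthetic-cohort generator with dual-confirmation
    labels (maternal button presses validated by ultrasound intervals),
    non-overlapping 5 s segmentation with subject-independent splitting,
    quaternion virtual-rotation augmentation of the minority class, adaptive
    k-means undersampling of the majority class with a composite
    Manhattan/cosine metric, STFT log-spectrogram featurization, compact
    convolutional classifiers trained by knowledge distillation with
    temperature scaling, INT8 post-training quantization with size
    accounting, and duty-cycle battery-life estimation for edge deployment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
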