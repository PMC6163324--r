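Package: canegait
Title: Segmentation of Cane-Assisted Gait from Strain and Gyroscope Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for segmenting cane-assisted gait from an instrumented
    cane that records strain-gauge loading and gyroscope anteroposterior
    (AP) angular velocity. Implements a multi-sensor matched-filter (MSMF)
    segmenter that anchors strides on normalized template correlation and
    extracts initial-contact (IC), terminal-contact (TC), peak-swing (PS)
    and end-contact (EC) events through a finite-state cycle validator;
    gyroscope peak-detection (GPD) baselines with several threshold
    calibration policies and an ROC threshold sweep; stride classification,
    stride-time variability and push-switch timing-error metrics; and a
    synthetic cane-gait simulator that produces recordings with ground-truth
    events across walking terrains so the whole pipeline can be exercised
    and validated without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
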