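Package: flyheart
Title: Automated Quantification of Drosophila Cardiac Dynamics from
    High-Speed Optical Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Frame-level heart-wall segmentation of high-speed optical
    recordings of beating Drosophila hearts with an attention U-Net on
    temporal three-frame stacks, extraction of calibrated lumen-diameter
    traces and annotated M-mode images, beat-level detection of diastolic
    and systolic intervals with the full cardiac statistic suite
    (diastolic/systolic diameters, fractional shortening, ejection
    fraction, heart period and rate, arrhythmia index, stroke volume,
    cardiac output, contractile latencies, tachy/brady event filters),
    and two age-classification pipelines (logistic classification on
    cardiac statistics with exact linear-model Shapley attributions, and
    a motion-keyframe convolutional video classifier), exercised
    end-to-end on a seeded synthetic beating-heart simulator with
    ground-truth masks and beat tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tiff,
    png,
    yaml,
    jsonlite,
    glmnet,
    pROC,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
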