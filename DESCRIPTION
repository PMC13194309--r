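Package: suturesegkit
Title: Multimodal Surgical Gesture Segmentation Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for frame-wise surgical gesture recognition from
    multimodal operating-room data streams: cleaning and smoothing of
    6-DoF tool pose tracks (symmetry-flip disambiguation, gap-limited
    imputation, Savitzky-Golay filtering), 21-joint hand pose handling,
    a multi-stage temporal convolutional network (MS-TCN++) for temporal
    action segmentation with the standard cross-entropy plus truncated
    mean-squared smoothing loss, logit-averaging model ensembles with
    neighbour-based prediction smoothing, segmental evaluation metrics
    (edit score, overlap F1), leave-one-user-out cross-validation, paired
    Wilcoxon signed-rank comparisons, and a multi-surgeon synthetic
    operating-room simulator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
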