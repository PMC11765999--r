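Package: blinkdetect
Title: Blink Detection in Cropped Eye Video via 3D Subsequence Classifiers and Prediction Accumulators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects eye blinks in pre-cropped single-eye grayscale video and
    scores the detections at the blink-event level. A subsequence classifier
    (a simple 3D convolutional network, a 3D convolutional autoencoder with a
    classifier coupled to its latent space, or a compact 3D residual network)
    is slid over the frame stack with dense overlap; per-window votes are
    summed into a per-frame prediction accumulator which is cleaned by
    grayscale morphological closing, split into candidate events by 1D
    watershed segmentation of its negative, and thresholded into inclusive
    start/end blink intervals. Evaluation matches predicted to annotated
    intervals by intersection-over-union, builds the binary correspondence
    matrix and derives event-level FN/FP/TP counts, accuracy and F1. A
    procedural synthetic eye-video generator with matching annotations makes
    the whole pipeline testable without any recorded video.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    png,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
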