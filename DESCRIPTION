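Package: kymoradon
Title: Red Blood Cell Velocimetry from Line-Scan Images by Sobel
    Filtering and Iterative Radon Transforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Measures red blood cell velocity from line-scan (kymograph)
    space-time images acquired with two-photon or bright-field microscopy.
    Diagonal RBC streaks are enhanced with a vertical (temporal) Sobel
    filter, and the streak angle is found as the maximizer of the Radon
    projection variance using a coarse-to-fine iterative search that
    evaluates four projection angles per iteration while halving the angle
    step. Also provides the measurement-design calculus relating angle
    step-size, detectable fractional velocity change, pixel-resolution
    limits, and acquisition-speed rescaling, a windowed pipeline for long
    line-scan sequences with outlier flagging and smoothing, a synthetic
    streak-image generator with ground truth and artifact injection, and a
    command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
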