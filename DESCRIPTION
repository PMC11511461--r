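Package: pupilgaze
Title: Gated Pupil Segmentation and Polynomial Gaze Mapping for Head-Mounted Eye Tracking
Version: 0.1.0
Authors@R:
    person("pupilgaze", "developers", email = "dev@pupilgaze.org", role = c("aut", "cre"))
Description: A head-mounted eye-tracking pipeline built around a compact
    encoder-decoder pupil-segmentation network with an eye-closure branch
    that gates the decoder, content-aware reassembly (CARAFE) upsampling,
    moment-based pupil ellipse extraction, six-point second-order polynomial
    gaze calibration, and the standard gaze-estimation evaluation metrics
    (5-pixel detection rate, precision, RMSE, angular error, localization
    error). Includes a seeded synthetic near-infrared eye-image and
    gaze-session generator with exact ground truth, an Rcpp-backed training
    loop (Adam), and a command-line interface covering synthesis, training,
    calibration, tracking and evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
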