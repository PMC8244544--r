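Package: stomatrack
Title: Tracking and Quantification of Stomatal Dynamics from Microscope Video
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: An automatic analysis pipeline for time-lapse microscope videos of
    leaf surfaces: kernelized correlation filter (KCF) tracking of individual
    stomata, semantic segmentation of the stomatal aperture with a UNet-style
    encoder-decoder built from depthwise separable convolutions and
    squeeze-and-excitation channel attention, and downstream quantification of
    stomatal opening area (SOA) over time, its rate of change, and its
    correlation with gas-exchange series. Includes a ground-truthed synthetic
    scene generator so every stage is testable without real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    png,
    yaml,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
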