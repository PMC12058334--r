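Package: speckleflow
Title: Dynamic Speckle Simulation and Deep-Learning Classification of
    Arterial Flow States
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates defocused dynamic laser-speckle videos of artificial
    arteries under zero, low, medium and high flow, with pulsatile
    modulation and depth-dependent contrast loss.  Provides the full
    analysis pipeline around the simulator: chunk-based preprocessing of
    speckle videos, a 3D convolutional neural network classifier of flow
    state trained with Adam on categorical cross-entropy, a single-point
    calibrated laser speckle contrast analysis (LASCA) baseline together
    with its cross-depth calibration-transfer experiment, and confusion
    matrix / precision / recall / F1 reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    Rcpp,
    stats,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
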