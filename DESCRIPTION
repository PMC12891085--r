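Package: trdnet
Title: Lightweight Tomato Ripeness Detection Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds, profiles, trains at desk scale, and evaluates lightweight
    one-stage detectors for tomato ripeness grading in greenhouse scenes.
    Implements spatial and channel reconstruction convolution (SCRConv), the
    parameter-free SimAM attention mechanism derived from a per-neuron energy
    function, and the minimum-point-distance IoU (MPDIoU) bounding-box
    regression loss, together with a YOLOv8-style model builder with exact
    parameter and FLOP accounting, PASCAL VOC and YOLO annotation I/O, mosaic
    augmentation, a synthetic greenhouse-scene generator with pixel-verifiable
    ripeness labels, precision/recall/mAP evaluation, and Grad-CAM heatmaps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    utils,
    xml2,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
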