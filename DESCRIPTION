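Package: cathmtl
Title: Multi-Task Catheter Detection and Segmentation in X-Ray Fluoroscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint electrode detection (center heatmap plus box-size regression) and
    catheter segmentation for X-ray fluoroscopy, trained with a multi-level dynamic
    resource prioritization strategy that re-allocates learning effort to difficult
    samples and tasks using exponentially smoothed key performance indicators.
    Includes a synthetic fluoroscopy scene generator with exact ground truth, a
    compact CPU convolutional network engine (encoder, channel/spatial attention,
    top-down decoder, three prediction heads), CenterNet-style target rendering and
    penalty-reduced focal loss, BCE+IoU segmentation loss, heatmap decoding, and a
    COCO-style average-precision evaluator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
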