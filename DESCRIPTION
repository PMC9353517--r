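Package: vineseg
Title: Grape Cluster Instance Segmentation with an Attention-Enhanced Mask R-CNN
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Trainable instance segmentation of grape clusters in field
    images. Implements a ResNet50 feature pyramid backbone augmented with
    efficient channel attention and dense upsampling convolution, Mask
    R-CNN style region-proposal, box and mask heads with the summed
    three-term loss, LabelMe polygon annotation handling including
    group-id merging of occlusion-split clusters, conversion to COCO
    JSON, a COCO-style AP/AR evaluator, and a synthetic vineyard scene
    generator so the whole pipeline is testable end-to-end on a CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
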