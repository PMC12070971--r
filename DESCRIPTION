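Package: sddetect
Title: Single-Class Dense Object Detection with Occlusion-Aware Losses
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for detecting densely packed, mutually occluding animals in
    images from intensive livestock systems. Implements the Overlap Ratio
    occlusion statistic and dense-subset stratification, an occlusion-aware
    composite loss (CIoU attraction plus RepGT/RepBox repulsion with a
    smoothed-log penalty), Haar wavelet-enhanced convolution blocks, an
    attention module fusing low-level detail with high-level semantics, a
    lightweight weight-shared detection head, COCO-style average-precision
    evaluation, and a deterministic generator of synthetic crowded scenes with
    YOLO-format annotations. A small CPU neural-network engine with explicit
    backward passes supports toy-scale training end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
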