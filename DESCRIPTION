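Package: wetbird
Title: Small-Object Detection Toolkit for Wetland Bird Monitoring Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained convolutional detection stack for small, low-contrast
    avian targets in cluttered wetland imagery. Implements receptive-field coordinate
    attention convolutions (RFCAConv, C2f_RFCA), large separable kernel attention
    (LSKA) fused into spatial pyramid pooling, a P2-augmented bidirectional feature
    pyramid neck, and content-aware feature reassembly (CARAFE) up-sampling, assembled
    into an anchor-free single-class detector with parameter and FLOP accounting,
    YOLO-format dataset handling, an offline augmentation pipeline, a synthetic
    wetland-scene generator with exact ground truth, COCO-style evaluation metrics,
    and a desk-scale training loop with hand-derived backpropagation in
    'RcppArmadillo'.
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
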