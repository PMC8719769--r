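Package: davsnet
Title: Dense Aggregation Encoder-Decoder Network for Retinal Vessel
    Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Re-implementation of DAVS-Net, a densely aggregating
    encoder-decoder convolutional network for semantic segmentation of
    retinal blood vessels in fundus photographs. Provides a symbolic layer
    graph with shape propagation and per-layer trainable-parameter audits
    against the published architecture table, an executable pure-R model
    (dense concatenation, 1x1 bottlenecks, max-pooling index transfer to
    the decoder, per-pixel softmax), the published training recipe
    (median-frequency-balanced weighted cross-entropy, Adam, leave-one-out
    splitting, rotation/brightness augmentation), field-of-view restricted
    evaluation metrics (sensitivity, specificity, accuracy, ROC and
    precision-recall areas), and a synthetic fundus image generator with
    pixel-perfect vessel and field-of-view ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
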