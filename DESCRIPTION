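Package: litessl
Title: Semi-Supervised Medical Image Classification with Contrastive
    Pretraining of a Light Vision Transformer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-supervised image classification for label-scarce settings
    such as medical imaging. A light one-block vision transformer encoder is
    pretrained on unlabeled images with a SimCLR-style contrastive objective
    (stochastic augmentation pairs, cosine similarity, normalized
    temperature-scaled cross-entropy), then a deep multi-layer-perceptron
    classifier is fine-tuned on a small labeled subset. Includes the
    stratified train/test and labeled-ratio split protocol, a synthetic
    image generator for end-to-end testing, per-class and macro evaluation
    metrics, and an ablation harness comparing a frozen-encoder linear probe
    against the full pipeline. All forward and backward passes are
    implemented in base R linear algebra with analytically derived gradients.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    ggplot2,
    generics,
    rlang,
    withr,
    nnet,
    jsonlite,
    EBImage
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    png,
    yaml,
    optparse
Config/testthat/edition: 3
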