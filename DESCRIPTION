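Package: ctedge
Title: Edge-Aware Segmentation of CT-Like Images with Compact Convolutional Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for edge-oriented segmentation of 2-D grayscale
    computed-tomography-like images. Provides a seeded synthetic phantom
    generator with exact ground truth, edge-point extraction with pattern
    clustering and noise-cluster elimination, feature-similarity weighting
    and edge-curve linking, a small fixed-architecture convolutional patch
    classifier, an encoder-decoder pixel-labeling network that unpools with
    stored max-pooling indices and aggregates context through dilated
    (atrous) convolutions, Dice and recall evaluation utilities, and a
    command-line interface. All networks train on a single CPU; the
    numerical core is implemented with 'RcppArmadillo'.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    optparse,
    withr,
    png,
    tiff,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    EBImage
Config/testthat/edition: 3
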