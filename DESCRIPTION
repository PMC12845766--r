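Package: maunet
Title: Lightweight Asymmetric U-Net for Nucleus Segmentation with
    Balance-Aware Patch Augmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Binary semantic segmentation of cell nuclei in microscopy
    images. Implements a lightweight encoder-decoder convolutional network
    with an asymmetric channel schedule and skip connections, together with
    a class-imbalance-aware sliding-window patch extraction and augmentation
    stage (adaptive augmentation), a seeded training protocol (Adam with
    decoupled weight decay, stepwise learning-rate decay, early stopping,
    best-checkpoint selection), pixelwise evaluation metrics (precision,
    recall, F1, mean intersection-over-union), a reader for the 2018 Data
    Science Bowl folder layout, and a synthetic microscopy-image generator
    for fully reproducible end-to-end runs. The convolutional engine
    (forward pass and backpropagation) is implemented in the package using
    'RcppArmadillo'.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    png,
    tiff,
    yaml,
    jsonlite,
    EBImage,
    stats,
    utils,
    graphics,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
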