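Package: blurseg
Title: Anti-Aliased Blur-Attention Network for Cell Nucleus Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segmentation of cell nuclei in 2-D microscopy images with an
    encoder-decoder convolutional network built from anti-aliased (blur
    pooling) primitives: channel and spatial blur-attention modules in the
    downsampling path, a pyramid blur pooling module in the upsampling path,
    and auxiliary strided skip connections. Includes image preprocessing
    (grayscale conversion, biorthogonal wavelet denoising, patch tiling,
    augmentation), pixel-level (Dice, precision, recall, F1) and object-level
    (aggregated Jaccard index) evaluation, a seeded synthetic nuclei-scene
    generator for fluorescence- and histology-style images, training with
    pretraining and fine-tuning, and a command-line interface. The network,
    its layers and a minimal reverse-mode differentiation tape are implemented
    in R and C++.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    png,
    tiff,
    yaml,
    EBImage,
    optparse
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
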