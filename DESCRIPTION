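Package: repbnet
Title: Bilinear RepVGG Networks with Shuffle Attention for Individual
    Animal Identification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for recognising individual animals from paired face
    views with a bilinear (two-branch) convolutional network built from
    RepVGG blocks and shuffle-attention modules.  Implements the
    structural reparameterization that fuses each multi-branch training
    block (3x3 conv + 1x1 conv + identity, each batch-normalised) into a
    single 3x3 convolution for inference, losslessly up to floating-point
    error.  Also provides the dataset-construction pipeline around the
    network: histogram-similarity deduplication of video frames,
    stochastic photometric augmentations, paired-view sampling, a seeded
    training loop (Adam with cosine-annealed learning rate), macro-averaged
    multi-class evaluation metrics, and a fully procedural synthetic
    two-view image generator so that every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
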