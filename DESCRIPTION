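Package: dcsanet
Title: Lightweight Encoder-Decoder Semantic Segmentation for Crop/Weed Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements DCSAnet, a lightweight encoder-decoder convolutional
    network for pixel-level classification of field images into soybean,
    graminoid weed, broadleaf weed and soil background. Provides the DCA
    feature-extraction blocks (inverted-residual bottlenecks with split
    asymmetric depthwise convolutions and channel shuffling), a guided
    feature-aggregation decoder with ablation variants, analytic parameter
    and FLOP accounting, a LabelMe-based preprocessing pipeline (polygon
    rasterization, random cropping, five-fold augmentation, 6:3:1 splits),
    a synthetic field-scene generator for fully reproducible testing, and a
    seeded training/evaluation loop (cross-entropy loss, Adam, mean
    intersection-over-union) built on a self-contained reverse-mode
    autodifferentiation engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    graphics,
    jsonlite,
    mgcv,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
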