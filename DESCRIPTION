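Package: tcsrnet
Title: Lightweight Curing-Stage Recognition Networks with Ghost
    Convolutions and Multi-Scale Adaptive Attention
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds, profiles and trains TCSRNet, a lightweight
    convolutional classifier for the ten flue-curing stages of tobacco
    leaves, together with its MobileNetV3-Small baseline and ablation
    variants. The improved inverted-residual block replaces the 1x1
    expansion convolution with a four-branch Inception structure
    (1x1, 3x3, dilated 3x3, max-pool), projects through Ghost
    convolutions that synthesise half of their output maps with cheap
    depthwise filters, and re-weights features with a Multi-scale
    Adaptive Attention Module (MAAM) built from average, max and
    standard-deviation pooling with a gated channel/spatial fusion.
    Includes an exact parameter and FLOP profiler with a documented
    counting convention, a synthetic curing-stage leaf-image generator,
    an augmentation pipeline, and a small CPU training/evaluation loop
    with confusion-matrix metrics. All network forward and backward
    passes are implemented in base R on top of BLAS matrix products.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    png,
    yaml,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
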