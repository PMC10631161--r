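Package: adrenalseg
Title: Volumetric Segmentation of Adrenal Tumors with a DSConv-Transformer Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for volumetric segmentation of adrenal
    tumors in contrast-enhanced CT: synthetic abdominal phantom generation
    with ellipsoidal adrenal-style lesions, NIfTI-1 input/output and CT
    preprocessing (intensity windowing, in-plane downsampling, slice
    resampling, normalization), a 3D encoder-decoder segmentation network
    built from depthwise separable convolutions with a channel-token
    transformer bottleneck, Dice-loss training with the Adam optimizer and
    slab sampling, slab-wise whole-volume inference, the five standard
    segmentation metrics (Dice, IoU, Hausdorff distance, average surface
    distance, mean absolute error), and Levene/t-test method comparison with
    an ablation harness. The network forward and backward passes are
    implemented natively with compiled kernels for the convolutions.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    stats,
    graphics,
    grDevices,
    tools,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
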