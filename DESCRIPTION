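Package: dfaunet
Title: Dual-Stream Feature-Fusion Attention U-Net for Ultrasound Elastography Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Binary lesion segmentation for pseudo-color ultrasound elastography
    images with a dual-stream attention U-Net: a ConvNeXt convolutional encoder
    paired with a lightweight vision-transformer stream, a hybrid channel/spatial
    attention bottleneck, and a feature-enhanced residual decoder. Includes the
    Dice training loss, an evaluation suite (Dice, IoU, precision, specificity,
    95th-percentile Hausdorff distance), Grad-CAM decoder visualization, six-fold
    cross-validation bookkeeping, a synthetic elastography image generator, and a
    small reverse-mode automatic-differentiation engine with C++ convolution
    kernels that the networks are built on.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    EBImage
Config/testthat/edition: 3
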