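Package: rksegnet
Title: Runge-Kutta Segmentation Networks for 2D Medical Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds, trains and evaluates RKSeg semantic-segmentation networks,
    a family of encoder-decoder-free architectures that compute one time step of
    an s-stage Runge-Kutta method with each stage evaluated at a different
    spatial scale. Provides the six variants (orientation L/R crossed with
    backbones E/I/R), a closed-form trainable-parameter count with an
    instantiated-model cross-check, Dice + cross-entropy training on CPU via
    compiled convolution primitives, per-class Dice evaluation, a deterministic
    synthetic 2D segmentation data generator, and NIfTI/PNG dataset I/O in the
    Medical Segmentation Decathlon folder layout.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    RNifti,
    png,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
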