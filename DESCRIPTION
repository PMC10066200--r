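Package: lumident
Title: Retinex Decomposition and Self-Supervised Enhancement of Low-Light Dental Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for enhancing under-exposed RGB photographs of teeth and oral
    mucosa. Images are decomposed into reflectance and illumination following the
    retinex model S = r * l, either with a training-free chain built on the dark
    channel prior and transmission estimation, or with a pair of small
    convolutional networks trained self-supervised on a folder of images.
    Clinically oriented exponential weighting maps give the user direct control
    over output brightness without retraining. Includes an edge-aware
    total-variation illumination smoothness loss, full-reference (PSNR, SSIM) and
    no-reference (lightness order error) quality metrics, and a seeded generator
    of synthetic dental image triples for testing and desk-scale training.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    png,
    tiff,
    Rcpp,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
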