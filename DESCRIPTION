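Package: latentks
Title: Out-of-Distribution Detection for Grayscale Medical Images by GAN
    Inversion and Kolmogorov-Smirnov Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects out-of-distribution grayscale images (for example, lateral
    chest radiographs presented to a model trained on frontal views) by training
    a deep convolutional generative adversarial network on in-distribution
    images, reconstructing each test image through gradient-based latent-space
    inversion, and applying a two-sample Kolmogorov-Smirnov test between the
    pixel-intensity distributions of the reconstruction and the target. Includes
    classical Canny-edge and histogram-intersection baselines with F1-maximizing
    threshold search, a procedural phantom generator for frontal-like and
    lateral-like image families, and an evaluation harness producing
    accuracy/precision/recall/F1 sweeps and one-way ANOVA summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
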