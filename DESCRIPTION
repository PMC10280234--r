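Package: carnsr
Title: Channel-Attention Super-Resolution for Histopathology Image Patches
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Single-image super-resolution for stained-tissue patches using
    a channel-attention retention network: residual convolution blocks
    ending in a widened squeeze-and-excitation gate (bottleneck width
    following the sqrt(C) rule) chained inside a long residual skip, with
    sub-pixel shuffle upsampling for 2x, 3x, 4x and 8x. Includes the
    combined L1/MSE/SSIM training objective with analytic gradients and an
    ADAM trainer, PSNR/SSIM evaluation, bicubic high/low-resolution pair
    degradation, a whole-slide patch curation pipeline (blank filtering by
    white-pixel fraction and RGB-mean-distance ranking with a seeded
    train/test split), and a deterministic generator of histology-like
    fixture images so the full stack is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
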