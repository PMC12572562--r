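Package: woundseg
Title: Dual-Attention VGG16 U-Net for Wound Image Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Builds, trains and evaluates encoder-decoder convolutional networks
    for binary wound segmentation from RGB photographs. Implements the VGG16
    encoder / U-Net decoder family with two attention mechanisms on a purpose-built
    CPU engine: additive attention gates on the skip connections (spatial
    attention) and squeeze-and-excitation blocks after every encoder and decoder
    stage (channel recalibration). Includes the class-weighted cross-entropy
    objective, Dice and IoU metrics, patient-aware data splitting, Adam training
    with early stopping and fine-tuning, a seeded synthetic wound-scene generator
    for fully offline testing, and the paired-t-test model comparison procedure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    png,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
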