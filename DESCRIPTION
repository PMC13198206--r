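Package: classm
Title: Semi-Supervised H&E Tile Classification with Adaptive Stain Separation
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for semi-supervised classification of Hematoxylin & Eosin
    (H&E) histopathology tiles. Implements slide-level adaptive stain
    separation in optical-density space (PCA plane fitting with robust angle
    quantiles), a dual single-channel encoder classifier with a cross-stain
    triplet contrastive loss, pseudo-labeling with MixUp on separated stain
    channels, balanced-batch training with early stopping, and a forward
    Beer-Lambert simulator of H&E-like tiles with known ground truth for
    desk-scale testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    digest,
    jsonlite,
    png,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
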