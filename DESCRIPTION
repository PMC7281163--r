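Package: sonotype
Title: Cancer-Cell Invasiveness Classification from Acoustic-Trap
    Deformation Image Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies single cancer cells as highly or weakly invasive
    from paired bright-field photomicrographs taken with a single-beam
    acoustic tweezers (SBAT) trap off and on.  The paired images are
    contrast-stretched and encoded as one three-channel change image
    (trap-on in red, trap-off in green, their mean in blue), expanded by
    geometric augmentation, and classified with a shallow convolutional
    neural network trained with any of five gradient optimizers.
    Includes a synthetic deformed-cell image generator with ground-truth
    masks, grouped stratified k-fold cross-validation with set-based
    accuracy/precision/recall/F1 metrics, an optimizer hyper-parameter
    grid search, and a fluorescence cross-domain evaluation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    Rcpp,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
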