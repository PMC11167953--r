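Package: ddfreg
Title: Deformable Multi-Modal Registration of Histology and Specimen
    Snapshot Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Deformable two-dimensional registration between macroscopic
    tissue-specimen snapshot images and H&E histology images. A
    convolutional encoder-decoder predicts a dense displacement field
    that warps the moving image onto the fixed image through a
    differentiable spatial transformer. Training is either unsupervised,
    driven by a histogram-based mutual-information similarity, or
    supervised, driven by mean squared error against ground-truth
    snapshot labels; both add a smoothness regulariser on the field.
    Includes synthetic elastic-deformation augmentation (Gaussian-smoothed
    random displacement fields), modality-specific grayscale conversion,
    a paired multi-modal phantom generator for fully reproducible
    experiments, and an evaluation suite (Dice overlap, mutual
    information, Mann-Whitney U comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    graphics,
    grDevices,
    jsonlite,
    png,
    Rcpp,
    stats,
    tiff,
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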