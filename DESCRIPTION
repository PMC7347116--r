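Package: mngdetect
Title: Automated Detection of Multinucleated Germ Cells in Histological
    Sections
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A fully automated pipeline for detecting multinucleated germ
    cells (MNGs) in hematoxylin-stained fetal testis sections. Grayscale
    slide images at 1 micron per pixel are converted to per-pixel MNG
    likelihood heatmaps by a compact U-Net trained on MNG-centered panels
    with dihedral augmentation; heatmaps are post-processed into discrete
    detections with brightness and Green's-theorem area cutoffs; detections
    are scored against human annotations with object-level precision,
    recall and F1; and a batch-stratified five-fold protocol with a grid
    search over epoch and cutoff parameters selects and evaluates the final
    model. A synthetic-histology generator with known ground truth makes
    every stage testable without real slides.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
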