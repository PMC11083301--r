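Package: marrowmeter
Title: Automated Bone Marrow Cellularity Assessment from H&E Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies bone marrow cellularity from haematoxylin-eosin
    histology images by patch-based semantic segmentation of hematopoietic
    versus adipose tissue with a fully convolutional network, following the
    tile/stitch/ratio workflow used in digital-pathology practice. Includes
    reading and writing of QuPath-style colour-coded label masks, an
    ignore-class-masked cross-entropy training loop with a compact CNN engine
    (RcppArmadillo), whole-slide tiling and overlay rendering, the cellularity
    ratio, method-agreement statistics (Lin's concordance correlation
    coefficient with Fisher-z confidence intervals and Altman grading,
    Bland-Altman limits of agreement), and a seeded synthetic histology
    generator with known ground truth for validation without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ggplot2,
    jsonlite,
    png,
    tiff,
    withr,
    yaml,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
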