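Package: TMAscreen
Title: Pre-Selection of Tissue MicroArray Punching Areas in H&E Slides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Semi-automatic classification of hematoxylin-eosin stained
    breast-tissue slide tiles as affected (tubular carcinoma), unaffected,
    or non-informative, to pre-select punching areas for Tissue MicroArray
    construction. Implements quadratic three-anchor stain-intensity
    calibration, punching-grid tiling, k-means color segmentation of
    nuclei, moment-ellipse morphometry of nuclear agglomerates with a
    lymphocyte size filter, and a model-independent local-thickness
    (largest inscribed disk) test separating single- from double-layer
    epithelium. Ships a synthetic H&E scene generator with per-tile ground
    truth and a confusion-matrix evaluation harness with truncated
    percentage metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    EBImage,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
biocViews: CellBiology, Classification, Visualization
RoxygenNote: 7.3.3
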