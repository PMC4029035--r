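Package: annotseg
Title: Annotation-Guided DNA Copy-Number Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Supervised analysis of DNA copy-number profiles (aCGH, SNP
    array log ratios). Computes exact least-squares piecewise-constant
    segmentations for every model size by dynamic programming, scores
    models against expert-drawn breakpoint annotations with a zero-one
    annotation error, selects the displayed model via max-margin interval
    regression on a learned penalty scale, falls back to an
    annotation-constrained exact segmentation when no unconstrained model
    is consistent, calls per-segment copy-number state from thresholds
    learned on copy-number annotations, and exports UCSC genome-browser
    tracks (bedGraph/BED). Includes a synthetic profile generator with
    known ground truth for validation.
License: GPL-3
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
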