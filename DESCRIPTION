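Package: methylCUP
Title: Tissue-of-Origin Prediction from DNA Methylation Images
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts the organ of origin of a tumour from DNA methylation
    microarray beta values. The pipeline filters and imputes a probe-by-sample
    beta matrix, selects class-specific differentially methylated CpG panels
    separately within non-squamous and squamous tumour groups
    (median-difference ranking with Mann-Whitney U screening), embeds each
    panel onto a 2-D pixel grid by iterative rank-matching swap optimisation
    (IGTD), renders per-sample grayscale methylation images, and classifies
    the merged images with a small vision transformer whose final-layer
    attention can be visualised. A seeded synthetic-cohort generator with
    implanted differentially methylated probes makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    yaml,
    png,
    EBImage,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
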