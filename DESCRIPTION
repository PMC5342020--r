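Package: cnacohort
Title: Cohort-Level Somatic Copy-Number Aberration and Breakpoint Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Cohort-level analysis of somatic copy-number aberrations (CNAs)
    from array-CGH log2 ratios: per-sample circular-binary-segmentation-style
    change-point detection with SD-undo pruning, mixture-model calling of
    loss/neutral/gain/amplification states with class posteriors, reduction of
    probe-level calls to co-aberrant regions, detection of CNA-associated
    chromosomal breakpoints with a binomial recurrence null and a discrete
    (Tarone-Gilbert) false discovery rate for recurrent breakpoint genes,
    permutation-FDR association tests of regions against clinical groups and
    disease-free survival, chromosomal-instability scores, mutation-matrix
    construction with pathway pooling and co-occurrence tests, and a synthetic
    array-CGH cohort generator with full ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    survival,
    ape,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse,
    jsonlite
Config/testthat/edition: 3
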