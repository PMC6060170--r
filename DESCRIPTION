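Package: plasmaCNA
Title: Copy-Number Alteration Detection in Plasma Cell-Free DNA from
    Low-Coverage Whole-Genome Sequencing Bin Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects tumour-derived copy-number alterations (CNAs) in plasma
    cell-free DNA profiled on a low-coverage whole-genome sequencing (NIPT-style)
    platform. Reads are aggregated on a fixed 50-kb genomic bin grid, adjusted for
    GC bias with a sample-specific LOESS fit, smoothed against a reference panel
    by principal-component projection removal, and segmented with circular binary
    segmentation. Segments are classified with a CADET-style decision layer
    combining a MAD-scaled z-statistic, a Gaussian log odds ratio, and a bootstrap
    confidence level, with whole-chromosome versus subchromosomal scoping and a
    10-Mb reporting rule. Also provides a ridge-regression tumour-fraction
    estimator trained on regional autosomal depth, a negative-binomial synthetic
    cfDNA simulator with GC and batch artefacts for end-to-end validation, and
    cohort-level detection tables with Kaplan-Meier / log-rank survival
    stratification by CNA positivity.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    rlang,
    stats,
    survival,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
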