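Package: clearseq
Title: Molecular Subtyping of Clear-Cell Renal Cell Carcinoma from Bulk Expression
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Assigns the ccrcc1-4 transcriptomic subtypes of clear-cell renal
    cell carcinoma from bulk RNA-seq count matrices. Implements the full
    pipeline: CPM-based gene filtering and library-depth sample filtering,
    median-of-ratios size factors with a variance-stabilizing transform,
    parametric empirical-Bayes batch correction, median (or mean) scoring of
    the eight subtype gene signatures, a percentile-threshold decision tree
    with fixed-cutoff mode for small cohorts, and a linear support vector
    machine for single-sample classification with calibrated confidence
    values. Includes a negative-binomial cohort simulator with planted
    subtype and batch structure so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    jsonlite,
    quadprog
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    withr
Config/testthat/edition: 3
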