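Package: cellvar
Title: Differential Cell-to-Cell Expression Variability for Single-Cell RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies gene expression noise (eta-squared, the squared
    coefficient of variation) from two-condition single-cell RNA-seq count
    matrices and classifies variation-increased and variation-decreased genes
    by the mean +/- SD rule on the change in coefficient of variation between
    conditions. Provides the surrounding pipeline: count-matrix input/output,
    cell and gene quality filters, TPM normalisation, a rank-based two-group
    differential-expression stand-in, 2x2 overlap enrichment (chi-square,
    Fisher exact, hypergeometric over-representation with Benjamini-Hochberg
    adjustment), PCA-based condition-separation diagnostics, counting of
    regulatory ChIP-seq peaks near transcription start sites, and a
    negative-binomial synthetic-data generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
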