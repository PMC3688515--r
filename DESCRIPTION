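Package: fnrregulon
Title: Genome-Scale Analysis of FNR Binding, NAP Occlusion, and Regulon Categories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for dissecting the regulon of the
    anaerobic transcription factor FNR (and, by construction, any bacterial
    TF with a gapped-palindrome motif) from ChIP enrichment data. Provides
    position-weight-matrix construction and genome scanning with exact
    score-distribution p-values, precision-recall threshold selection
    against ChIP peaks, per-peak multi-site calling (SD-gap plus a
    fixed-constant Grubbs screen), background-median occupancy
    normalization for titration and strain comparisons, silent-site /
    nucleoid-associated-protein occlusion statistics, operon-level
    differential-expression consensus, and a seven-category regulon
    classifier. A synthetic-data module generates genomes with planted
    binding sites under a Langmuir occupancy model, NAP occlusion regions,
    probe-array and read-density ChIP readouts, and replicated expression
    matrices with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    limma,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
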