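Package: ribote
Title: Translation Efficiency and Coding-Potential Analysis for Ribosome
    Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrated analysis of paired RNA-seq and Ribo-seq count data
    for studies of translational regulation in microbes, with an emphasis on
    archaeal oxidative-stress experiments. Provides TPM quantification with a
    detection filter, negative-binomial Wald tests of differential transcript
    abundance and ribosome occupancy, a translation-efficiency (TE)
    interaction test, a ribosome footprint-length-distribution classifier of
    small-RNA coding potential with read-count threshold calibration, a small
    open reading frame (smORF) scanner with alternative start codons, sRNA
    target-overlap and category-enrichment statistics, a negative-binomial
    synthetic-data generator that emulates the statistical structure of such
    experiments, and an end-to-end pipeline driver. All user-facing functions
    take data frames and return tibbles so analyses compose with the pipe.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    Biostrings,
    DESeq2,
    GenomicRanges,
    IRanges,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
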