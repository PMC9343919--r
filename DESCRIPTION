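Package: hybridmeth
Title: Methylome and Transcriptome Comparison of an Interspecific Hybrid
    and Its Parents
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing DNA methylation and transposable-element
    (TE) and gene expression between an interspecific F1 hybrid and its two
    parental genomes, modelled on a peach x almond cross. Implements
    per-feature weighted methylation levels in the CG, CHG and CHH contexts
    with coverage filters, bisulfite conversion-rate estimation from an
    unmethylated chloroplast, a fixed-window Fisher's exact differentially
    methylated region (DMR) caller with Benjamini-Hochberg correction and
    bin merging, negative-binomial differential expression with a
    three-genotype expression-pattern classifier, qPCR relative
    quantification by the 2^-ddCt method, and a synthetic-data generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    tools,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    withr
Config/testthat/edition: 3
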