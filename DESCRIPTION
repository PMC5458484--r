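Package: lncscreenr
Title: Screening, Filtration and Classification of Putative Long Non-Coding RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Identifies putative long non-coding RNAs (lncRNAs) from an
    assembled transcriptome by classifying assembled transfrags against a
    reference annotation (Cuffcompare-style class codes), applying a
    strand-aware filtration cascade (protein-coding extended-TSS exclusion,
    small-RNA exclusion, minimum spliced length), gating on coding
    probability, quantifying gene-level FPKM with cutoff-aware group
    summaries, integrating histone-mark ChIP-seq peaks at extended TSS
    regions, calling group-enriched lncRNAs and enhancer-RNAs, annotating
    segmented data and TAD-constrained Hi-C interactions, and emitting the
    filtration ledger, pie-matrix statistics and a comprehensive per-lncRNA
    feature report. Includes a deterministic synthetic-fixture generator
    with planted ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors,
    BiocGenerics,
    Biostrings,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
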