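Package: MPRAcard
Title: Quantification and Variant-Effect Analysis for Cardiac Enhancer MPRAs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end toolkit for massively parallel reporter assay (MPRA)
    studies of cardiac enhancers and noncoding de novo variants. Provides
    seeded simulators for every pipeline input, oligo library designers
    (self-priming STARR pairs, tiling-deletion mutagenesis, REF/ALT variant
    pairs with Hamming-separated barcodes), depth-normalized activity
    quantification, a negative-binomial active-enhancer caller, paired
    REF/ALT differential-activity classification, rank-based enrichment
    scores with permutation p-values, exact PWM motif-change analysis, and a
    LASSO model (EpiCard) that scores genomic windows from epigenomic
    annotation-overlap features, with trio-cohort burden statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    MASS,
    rtracklayer,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
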