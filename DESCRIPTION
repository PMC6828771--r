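Package: WoundChrom
Title: Chromatin-State Dynamics and the Timing of Wound-Induced Transcription
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrative analysis of histone-modification ChIP-seq and RNA-seq
    time courses around wounding. Builds strand-aware promoter+gene-body
    analysis windows, assigns replicate-consistent peak calls to genes, derives
    histone-H3-normalized mark enrichment levels, calls differential marking
    from MA-rescaled log ratios, identifies wound-responsive genes with a
    negative-binomial conditional exact test and TMM normalization, orders
    induction-timing K-means clusters, and quantifies mark/timing relationships
    (representation factors with hypergeometric tails, rank-LOESS timing
    curves, acetylation/H3K4me3 precedence). Includes a fully deterministic
    synthetic-data generator with planted ground truth so the whole pipeline is
    testable end to end, and a treatment-versus-control contrast mode.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    MASS,
    jsonlite,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    optparse,
    knitr,
    rmarkdown
biocViews: Epigenetics, ChIPSeq, RNASeq, TimeCourse, DifferentialExpression,
    HistoneModification, Clustering
Config/testthat/edition: 3
RoxygenNote: 7.3.3
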