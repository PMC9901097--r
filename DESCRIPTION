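Package: OrthoDEO
Title: Cross-Species Orthogroup Differential Expression Along Leaf
    Developmental Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Comparative analysis of leaf developmental transcriptomes
    across C3, Proto-Kranz and C4 grasses assembled de novo. Provides
    curation of assembled transcript sets (top-isoform selection,
    redundancy collapse, single-best-ORF and expression filters, assembly
    statistics), orthogroup-level expression aggregation with annotation
    transfer, a self-contained differential-expression engine (CPM, TMM
    normalization, moment-based dispersion estimation, conditional
    negative-binomial exact test, Benjamini-Hochberg FDR) for
    within-species segment contrasts and cross-species orthogroup
    contrasts, pathway-level profiling, z-score expression-pattern
    conservation calls, sink/source zone classification, GO enrichment
    with the elim decorrelation algorithm, PCA loading-set enrichment,
    and a negative-binomial synthetic-data generator with planted ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
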