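Package: duoReg
Title: Motif Variants, Occupancy Classes and Proximity Enrichment for
    Co-Binding Transcription Factors
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for dissecting how two transcription factors
    that recognise the same DNA element (the extended nuclear-receptor
    half-site TCAAGG(T/C)CA, bound by the orphan receptors Esrrb and Nr5a2
    in mouse embryonic stem cells) divide and share their genomic targets.
    Provides exact and one-mismatch consensus scanning with a free seventh
    base, position-weight-matrix scoring, seventh-base preference profiles
    along binding-ratio-ranked regions, replicate-reproducible peak logic,
    a negative-binomial differential binding/expression test, K-means
    occupancy dependence classes with enrichment-driven choice of k,
    motif-pair spacing enrichment against a randomised background with
    Poisson tail probabilities, hypergeometric proximity enrichment of
    differentially expressed genes around region classes over a distance
    grid, Gaussian-process trends of binding change versus motif
    composition, and a binding-cooperativity (greater-than-additive) test.
    A fully deterministic synthetic-data generator with planted ground
    truth exercises every stage end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    MASS,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    BiocGenerics,
    DESeq2,
    rtracklayer,
    jsonlite
biocViews: ChIPSeq, Transcription, MotifAnnotation, Clustering,
    DifferentialExpression, GeneRegulation, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
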