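Package: methyLink
Title: Methylome-Transcriptome-Pathology Integration for RRBS Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrates reduced representation bisulfite sequencing (RRBS)
    methylomes with matched transcriptomes and neuropathology in mouse models
    of amyloidosis. Provides covariate-adjusted differential-methylation
    calling on per-CpG read counts, discovery of expression-linked CpGs
    (ECpGs) by local and distal regression of variance-stabilized expression
    on percent methylation, chaining of ECpGs into differentially methylated
    regions, permutation enrichment of ECpGs near distal enhancer and CTCF
    elements, read-depth-weighted binomial modelling of methylation against
    amyloid plaque burden, and construction of choline-protected gene sets.
    A full synthetic-data generator reproduces the two-genotype, two-diet,
    four-age, two-sex, two-region study design with planted effects so every
    stage carries parameter-recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
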