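Package: dupexpr
Title: Gene Duplication and Differential Expression Analysis for
    Two-Condition Transcriptomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Post-assembly analysis toolkit for two-condition (e.g. salinity
    shift) transcriptomes of microbial eukaryotes. Collapses predicted ORFs
    into genes by shared exact nucleotide stretches, screens out prokaryotic
    contaminant transcripts by local similarity and abundance/intron
    evidence, computes TPM and negative-binomial differential-expression
    calls with multi-caller consensus, detects recently duplicated genes by
    conspecific similarity ranking and bootstrap-supported phylogenetic
    exclusivity, tests functional-class (COG) enrichment with the
    hypergeometric distribution, quantifies the association between
    duplication and expression change including a cluster-randomization
    null for mixed-direction duplicate clusters, screens lateral
    gene-transfer candidates, and scans proteins for short wildcard motifs
    and ER-retention signals. A synthetic-data generator with known ground
    truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    Biostrings,
    SummarizedExperiment,
    ape,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
biocViews: Transcriptomics, DifferentialExpression, Phylogenetics,
    GeneDuplication, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
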