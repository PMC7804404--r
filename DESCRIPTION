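Package: chromshift
Title: Differential Chromatin Interactions, TAD Boundaries and A/B
    Compartments with Multi-Omic Integration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical analysis of activation-induced chromatin remodelling
    from Hi-C, ATAC-seq and RNA-seq count data. Counts Hi-C read pairs into
    genomic bin pairs, filters them against the inter-chromosomal background
    ligation frequency, normalizes abundance-dependent biases with LOESS
    offsets and tests bin pairs for differential interactions with a negative
    binomial quasi-likelihood framework, aggregating significant bin pairs
    into clusters with cluster-level FDR control. Calls topological domains
    from insulation profiles, tests TAD boundary strength through the
    upstream/downstream contact ratio, derives A/B compartments from the
    leading eigenvector of the observed/expected contact correlation matrix
    and classifies compartment flips. Integrates differential accessibility
    and expression with the interaction calls through gene-regulatory
    interaction networks, coupling tests and eRNA analysis. Ships a synthetic
    multi-omic data generator with planted TADs, loops, compartments and
    batch effects so every stage is testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    limma
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
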