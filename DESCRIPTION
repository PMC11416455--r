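Package: EVmiRDyn
Title: Temporal and Genotype Analysis of Extracellular-Vesicle miRNA
    Expression in Brain Organoids
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Statistical pipeline for small-RNA sequencing counts of
    extracellular-vesicle miRNAs collected across brain-organoid
    development. Implements trimmed-mean-of-M-values (TMM) normalization
    and log2 counts-per-million, negative-binomial quasi-likelihood F-tests
    with empirical-Bayes moderated quasi-dispersions for temporal and
    genotype contrasts, Ward clustering of standardized temporal profiles,
    ubiquitous-expression calling, genomic miRNA-cluster summarization, and
    miRNA-target pathway over-representation analysis calibrated by a
    size-matched permutation null. Includes a negative-binomial synthetic
    count generator that emulates the two-genotype, two-region, four
    timepoint organoid design with ground-truth labels for recovery
    testing.
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
    rtracklayer,
    fgsea,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    limma,
    mclust
Config/testthat/edition: 3
biocViews: Normalization, DifferentialExpression, Clustering,
    GeneSetEnrichment, Sequencing, miRNA
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
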