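## Genotype layer: union of RTT-vs-IC hits across condition cells and
## summarization of genomic miRNA clusters (C14MC-style loci).

#' Union of genotype-differential miRNAs across condition cells
#'
#' Combines the per-timepoint RTT-vs-IC `DETable`s of [genotypeDE()] into
#' the set of miRNAs significant (BH q < `alpha`) in at least one
#' comparison, together with the log2 fold-change matrix (rows = union
#' miRNAs, columns = comparisons) and per-comparison significance flags —
#' the data behind a fold-change heatmap with significance borders.
#'
#' @param deTables named list of `DETable` data.frames sharing one miRNA
#'   universe (see [genotypeDE()]).
#' @param alpha FDR threshold (default 0.05).
#' @return list with `mirna_ids` (the union), `log2fc` (matrix), and
#'   `significant` (logical matrix of the same shape).
#' @export
differentialUnion <- function(deTables, alpha = 0.05) {
    stopifnot(is.list(deTables), length(deTables) >= 1)
    ids0 <- deTables[[1]]$mirna_id
    for (tab in deTables)
        if (!setequal(tab$mirna_id, ids0))
            stop("DE tables must share the same miRNA universe")
    sig <- sapply(deTables, function(tab) {
        s <- !is.na(tab$q_value) & tab$q_value < alpha
        s[match(ids0, tab$mirna_id)]
    })
    sig <- matrix(sig, nrow = length(ids0),
                  dimnames = list(ids0, names(deTables)))
    lfc <- sapply(deTables, function(tab) tab$log2fc[match(ids0,
                                                           tab$mirna_id)])
    lfc <- matrix(lfc, nrow = length(ids0),
                  dimnames = list(ids0, names(deTables)))
    keep <- rowSums(sig) > 0
    list(mirna_ids = ids0[keep],
         log2fc = lfc[keep, , drop = FALSE],
         significant = sig[keep, , drop = FALSE])
}

#' Summarize a genomic miRNA cluster
#'
#' For the members of one annotated genomic cluster (shared `cluster_id` in
#' the annotation, e.g. the chr14q32 C14MC locus), reports: member counts,
#' how many members were tested and how many reached significance in at
#' least one RTT-vs-IC comparison, the fraction significant, the mean
#' member log2 fold-change per comparison, and each member's per-condition
#' mean log2 CPM ordered along the genome.
#'
#' @param x a normalized [MiRNAExperiment-class].
#' @param deTables named list of RTT-vs-IC `DETable`s (see [genotypeDE()]).
#' @param annotation a [GenomicRanges::GRanges] with metadata columns
#'   `mirna_id` and `cluster_id` (see [simulateAnnotation()] /
#'   [readAnnotation()]).
#' @param clusterId cluster label to summarize.
#' @param alpha FDR threshold (default 0.05).
#' @return list with `cluster_id`, `members`, `n_members`, `n_tested`,
#'   `n_significant`, `fraction_significant`, `mean_log2fc` (named per
#'   comparison), and `condition_means` (matrix, members ordered by genomic
#'   start x condition cells).
#' @export
clusterSummary <- function(x, deTables, annotation, clusterId,
                           alpha = 0.05) {
    stopifnot(is(x, "MiRNAExperiment"))
    mc <- S4Vectors::mcols(annotation)
    if (!all(c("mirna_id", "cluster_id") %in% colnames(mc)))
        stop("annotation needs 'mirna_id' and 'cluster_id' metadata columns")
    inCl <- !is.na(mc$cluster_id) & mc$cluster_id == clusterId
    if (!any(inCl)) stop("unknown cluster_id: ", clusterId)
    ann <- annotation[inCl]
    ann <- ann[order(start(ann))]
    members <- mc$mirna_id[inCl][order(start(annotation[inCl]))]

    universe <- deTables[[1]]$mirna_id
    tested <- members[members %in% universe]
    sigAny <- rep(FALSE, length(tested))
    meanLfc <- numeric(length(deTables))
    names(meanLfc) <- names(deTables)
    for (nm in names(deTables)) {
        tab <- deTables[[nm]]
        i <- match(tested, tab$mirna_id)
        sigAny <- sigAny | (!is.na(tab$q_value[i]) & tab$q_value[i] < alpha)
        meanLfc[nm] <- mean(tab$log2fc[i])
    }

    cd <- colData(x)
    cell <- paste(cd$genotype, cd$region, cd$timepoint, sep = "_")
    measured <- members[members %in% rownames(x)]
    lcp <- logCPM(x)[measured, , drop = FALSE]
    condMeans <- t(apply(lcp, 1, function(r) tapply(r, cell, mean)))
    condMeans <- matrix(condMeans, nrow = length(measured),
                        dimnames = list(measured, sort(unique(cell))))

    list(cluster_id = clusterId, members = members,
         n_members = length(members), n_tested = length(tested),
         n_significant = sum(sigAny),
         fraction_significant = if (length(tested)) sum(sigAny) /
             length(tested) else NA_real_,
         mean_log2fc = meanLfc, condition_means = condMeans)
}

#' Assign cluster membership by genomic containment
#'
#' Helper for annotations lacking an explicit `cluster_id`: labels every
#' miRNA whose interval falls entirely inside `locus` with `clusterId`.
#'
#' @param annotation a `GRanges` with a `mirna_id` metadata column.
#' @param locus a length-1 `GRanges` window (e.g. a chr14q32-style region).
#' @param clusterId label to assign.
#' @return the annotation with an updated `cluster_id` column.
#' @export
assignClusterByLocus <- function(annotation, locus, clusterId) {
    stopifnot(length(locus) == 1)
    hit <- IRanges::overlapsAny(annotation, locus, type = "within")
    mc <- S4Vectors::mcols(annotation)
    if (!("cluster_id" %in% colnames(mc)))
        mc$cluster_id <- NA_character_
    mc$cluster_id[hit] <- clusterId
    S4Vectors::mcols(annotation) <- mc
    annotation
}
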