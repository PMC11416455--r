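## Temporal-dynamics layer: selection of dynamically expressed miRNAs,
## standardized-profile Ward clustering, and ubiquitous-expression calling.

#' Union of temporally significant miRNAs across regions
#'
#' Takes the six pairwise timepoint `DETable`s per region (from
#' [temporalDE()]) and returns every miRNA with BH q below `alpha` in at
#' least one comparison of at least one region, flagging which region(s)
#' and comparison(s) triggered inclusion.
#'
#' @param deTables named list of regions, each a named list of exactly six
#'   `DETable` data.frames.
#' @param alpha FDR threshold (default 0.05).
#' @return data.frame with one row per dynamic miRNA: `mirna_id`, logical
#'   per-region columns, and a comma-separated `contrasts` flag column.
#' @export
dynamicMiRNAs <- function(deTables, alpha = 0.05) {
    stopifnot(is.list(deTables), length(deTables) >= 1)
    for (rg in names(deTables)) {
        if (length(deTables[[rg]]) != 6)
            stop("region '", rg, "' must supply exactly six contrasts; ",
                 "missing: ",
                 paste(setdiff(names(temporalContrasts()),
                               names(deTables[[rg]])), collapse = ", "))
    }
    hits <- list()
    for (rg in names(deTables)) {
        for (ct in names(deTables[[rg]])) {
            tab <- deTables[[rg]][[ct]]
            sig <- tab$mirna_id[!is.na(tab$q_value) & tab$q_value < alpha]
            if (length(sig))
                hits[[length(hits) + 1L]] <-
                    data.frame(mirna_id = sig, region = rg, contrast = ct)
        }
    }
    if (!length(hits)) {
        out <- data.frame(mirna_id = character(0))
        for (rg in names(deTables)) out[[rg]] <- logical(0)
        out$contrasts <- character(0)
        return(out)
    }
    hits <- do.call(rbind, hits)
    ids <- unique(hits$mirna_id)
    out <- data.frame(mirna_id = ids)
    for (rg in names(deTables))
        out[[rg]] <- ids %in% hits$mirna_id[hits$region == rg]
    out$contrasts <- vapply(ids, function(id) {
        h <- hits[hits$mirna_id == id, ]
        paste(paste(h$region, h$contrast, sep = ":"), collapse = ",")
    }, character(1))
    out
}

#' Standardize expression profiles to zero mean and unit variance
#'
#' Row-wise centering and scaling of a log2 CPM matrix, the standardization
#' applied before profile clustering. Constant rows cannot be scaled and are
#' mapped to all-zero profiles with a warning.
#'
#' @param m numeric matrix (miRNAs x samples).
#' @param sd `"sample"` (n-1 denominator, the default) or `"population"`
#'   (n denominator).
#' @return matrix of the same shape with rows of mean 0 and variance 1.
#' @export
scaleProfiles <- function(m, sd = c("sample", "population")) {
    sd <- match.arg(sd)
    m <- as.matrix(m)
    ctr <- m - rowMeans(m)
    n <- ncol(m)
    denom <- sqrt(rowSums(ctr^2) / if (sd == "sample") (n - 1) else n)
    const <- denom < 1e-12
    if (any(const)) {
        warning(sum(const), " constant profile(s) mapped to zeros")
        denom[const] <- 1
        ctr[const, ] <- 0
    }
    ctr / denom
}

#' Ward clustering of standardized temporal profiles
#'
#' Agglomerative hierarchical clustering with Euclidean distances and
#' Ward's minimum-variance linkage (`hclust` method `ward.D2`, which
#' operates on the distances themselves), cut into `k` groups. Each
#' cluster receives a monotonicity call from the sign pattern of the
#' consecutive timepoint differences of its mean profile within each
#' region: `increasing` when every within-region step is non-negative (and
#' at least one positive), `decreasing` when every step is non-positive,
#' otherwise `mixed`.
#'
#' @param m standardized matrix from [scaleProfiles()] (rows = miRNAs).
#' @param k number of clusters (default 3, the three temporal profile
#'   groups of the organoid study).
#' @param sampleInfo optional data.frame aligned with the columns of `m`
#'   carrying `region` and `timepoint`; required for monotonicity calls.
#' @return list with `labels` (named integer vector), `tree` (the `hclust`
#'   object), and `monotonicity` (per-cluster call, `NA` without
#'   `sampleInfo`).
#' @export
wardCluster <- function(m, k = 3L, sampleInfo = NULL) {
    m <- as.matrix(m)
    if (k > nrow(m)) stop("k exceeds the number of profiles")
    if (k < 1) stop("k must be >= 1")
    tree <- stats::hclust(stats::dist(m), method = "ward.D2")
    labels <- stats::cutree(tree, k = k)
    names(labels) <- rownames(m)
    mono <- rep(NA_character_, k)
    if (!is.null(sampleInfo)) {
        stopifnot(nrow(sampleInfo) == ncol(m))
        for (cl in seq_len(k)) {
            prof <- colMeans(m[labels == cl, , drop = FALSE])
            steps <- numeric(0)
            for (rg in c("dorsal", "ventral")) {
                keep <- sampleInfo$region %in% c("iPSC", rg)
                tp <- factor(sampleInfo$timepoint[keep], levels = TIMEPOINTS)
                tp <- droplevels(tp)
                if (nlevels(tp) < 2) next
                means <- tapply(prof[keep], tp, mean)
                steps <- c(steps, diff(as.numeric(means)))
            }
            mono[cl] <- if (!length(steps)) NA_character_
                else if (all(steps >= 0) && any(steps > 0)) "increasing"
                else if (all(steps <= 0) && any(steps < 0)) "decreasing"
                else "mixed"
        }
    }
    list(labels = labels, tree = tree, monotonicity = mono)
}

#' Call ubiquitously expressed miRNAs
#'
#' A miRNA is ubiquitous when its normalized log2 CPM reaches `threshold`
#' in every isogenic-control (IC) sample; the default threshold of 12
#' corresponds to roughly 4000 CPM.
#'
#' @param x a normalized [MiRNAExperiment-class], or a log2 CPM matrix.
#' @param threshold log2 CPM cut-off (default 12).
#' @param icSamples optional sample ids to use; defaults to the IC samples
#'   of the object. Required when `x` is a bare matrix.
#' @return character vector of ubiquitous miRNA ids.
#' @export
ubiquitousMiRNAs <- function(x, threshold = 12, icSamples = NULL) {
    if (is(x, "MiRNAExperiment")) {
        if (is.null(icSamples))
            icSamples <- colnames(x)[colData(x)$genotype == "IC"]
        m <- logCPM(x)
    } else m <- as.matrix(x)
    if (is.null(icSamples)) stop("icSamples required for a bare matrix")
    if (!length(icSamples)) stop("IC sample subset is empty")
    m <- m[, icSamples, drop = FALSE]
    rownames(m)[apply(m >= threshold, 1, all)]
}

#' Full temporal-dynamics analysis of the IC samples
#'
#' Runs [temporalDE()] for both regions, forms the dynamic union with
#' [dynamicMiRNAs()], standardizes the dynamic miRNAs' log2 CPM profiles
#' over all IC samples (ordered iPSC, dorsal, ventral, then by timepoint
#' and replicate), Ward-clusters them, and calls the ubiquitous set.
#'
#' @param x a normalized [MiRNAExperiment-class].
#' @param alpha FDR threshold (default 0.05).
#' @param k number of profile clusters (default 3).
#' @param ubiquitousThreshold log2 CPM cut-off (default 12).
#' @return list with `deTables`, `dynamic` (the union data.frame),
#'   `profiles` (standardized matrix), `clustering` (from [wardCluster()]),
#'   and `ubiquitous` (character vector).
#' @export
analyzeDynamics <- function(x, alpha = 0.05, k = 3L,
                            ubiquitousThreshold = 12) {
    deTables <- list(dorsal = temporalDE(x, "dorsal"),
                     ventral = temporalDE(x, "ventral"))
    dyn <- dynamicMiRNAs(deTables, alpha = alpha)
    cd <- colData(x)
    ic <- which(cd$genotype == "IC")
    ord <- ic[order(match(cd$region[ic], REGIONS),
                    match(cd$timepoint[ic], TIMEPOINTS), cd$replicate[ic])]
    icCols <- colnames(x)[ord]
    info <- data.frame(region = cd$region[ord], timepoint = cd$timepoint[ord])
    clustering <- NULL
    profiles <- NULL
    if (nrow(dyn) >= 2) {
        profiles <- scaleProfiles(logCPM(x)[dyn$mirna_id, icCols,
                                            drop = FALSE])
        clustering <- wardCluster(profiles, k = min(k, nrow(profiles)),
                                  sampleInfo = info)
    }
    list(deTables = deTables, dynamic = dyn, profiles = profiles,
         clustering = clustering,
         ubiquitous = ubiquitousMiRNAs(x, threshold = ubiquitousThreshold,
                                       icSamples = icCols))
}
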