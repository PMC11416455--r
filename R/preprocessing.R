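#' Filter lowly expressed miRNAs
#'
#' Keeps the miRNAs whose unnormalized counts-per-million reach `minCPM` in
#' at least `minSamples` samples, the conventional count-based expression
#' filter for small-RNA libraries. The sample set and the row order of the
#' survivors are unchanged, so the operation is idempotent.
#'
#' @param x a [MiRNAExperiment-class].
#' @param minCPM CPM threshold (default 1).
#' @param minSamples minimal number of samples at or above the threshold;
#'   defaults to the smallest condition-cell size in the design.
#' @return the filtered `MiRNAExperiment`.
#' @export
filterLowExpression <- function(x, minCPM = 1, minSamples = NULL) {
    stopifnot(is(x, "MiRNAExperiment"))
    cd <- colData(x)
    if (is.null(minSamples)) {
        cell <- paste(cd$genotype, cd$region, cd$timepoint)
        minSamples <- min(table(cell))
    }
    if (minSamples > ncol(x))
        stop("minSamples exceeds the number of samples")
    lib <- librarySizes(x)
    cpm <- sweep(counts(x), 2, lib, "/") * 1e6
    keep <- rowSums(cpm >= minCPM) >= minSamples
    if (!any(keep))
        warning("expression filter removed every miRNA")
    x[keep, ]
}

## 75th-percentile count fraction, the reference-selection statistic of the
## TMM workflow (quantile of counts scaled by library size).
.upperQuartileFraction <- function(counts, lib) {
    apply(sweep(counts, 2, lib, "/"), 2, stats::quantile, probs = 0.75)
}

## Single pairwise TMM factor: observation vs reference column.
.tmmPair <- function(obs, ref, libObs, libRef, trimM, trimA) {
    pos <- obs > 0 & ref > 0
    obs <- obs[pos]; ref <- ref[pos]
    pObs <- obs / libObs
    pRef <- ref / libRef
    M <- log2(pObs / pRef)
    A <- 0.5 * log2(pObs * pRef)
    ## delta-method (binomial) asymptotic variance of M
    v <- (libObs - obs) / (libObs * obs) + (libRef - ref) / (libRef * ref)
    finite <- is.finite(M) & is.finite(A) & v > 0
    M <- M[finite]; A <- A[finite]; v <- v[finite]
    n <- length(M)
    if (n < 2) {
        warning("fewer than 2 usable miRNAs for TMM; factor set to 1")
        return(1)
    }
    if (max(abs(M)) < 1e-6) return(1)
    loM <- floor(n * trimM) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trimA) + 1; hiA <- n + 1 - loA
    rM <- rank(M); rA <- rank(A)
    keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    if (sum(keep) < 2) {
        warning("fewer than 2 miRNAs left after trimming; factor set to 1")
        return(1)
    }
    f <- sum(M[keep] / v[keep]) / sum(1 / v[keep])
    2^f
}

#' Trimmed mean of M-values (TMM) normalization factors
#'
#' Estimates one relative scaling factor per sample from pairwise
#' comparisons against a reference column. For each sample, per-miRNA
#' log2 expression ratios (M) and average log2 abundances (A) are computed
#' on library-size-scaled proportions over the miRNAs positive in both
#' columns, doubly trimmed (30% of M values and 5% of A values by default,
#' each side), and combined by a precision-weighted mean whose weights are
#' the inverse delta-method variances of M. Factors are rescaled to
#' geometric mean 1, so they express composition corrections relative to
#' the sample set.
#'
#' @param x a [MiRNAExperiment-class] or a count matrix.
#' @param trimM,trimA two-sided trim fractions for M and A (defaults 0.30
#'   and 0.05).
#' @param refSample optional reference sample id; by default the sample
#'   whose 75th-percentile count fraction is closest to the mean of those
#'   fractions.
#' @return named numeric vector of TMM factors, geometric mean 1.
#' @export
tmmFactors <- function(x, trimM = 0.30, trimA = 0.05, refSample = NULL) {
    cnt <- if (is(x, "MiRNAExperiment")) counts(x) else as.matrix(x)
    if (ncol(cnt) < 2) stop("TMM requires at least 2 samples")
    lib <- colSums(cnt)
    if (any(lib <= 0)) stop("every sample must have a positive library size")
    if (is.null(refSample)) {
        f75 <- .upperQuartileFraction(cnt, lib)
        ref <- which.min(abs(f75 - mean(f75)))
    } else {
        ref <- match(refSample, colnames(cnt))
        if (is.na(ref)) stop("unknown reference sample: ", refSample)
    }
    f <- vapply(seq_len(ncol(cnt)), function(j) {
        if (j == ref) return(1)
        .tmmPair(cnt[, j], cnt[, ref], lib[j], lib[ref], trimM, trimA)
    }, numeric(1))
    f <- f / exp(mean(log(f)))
    stats::setNames(f, colnames(cnt))
}

#' Log2 counts per million on TMM-effective library sizes
#'
#' Computes `log2((count + p_j) / (L_j + 2 p_j) * 1e6)` per cell, where
#' `L_j` is the effective library size (column sum times TMM factor) and
#' `p_j` is the prior count scaled proportionally to the effective library
#' size (`priorCount * L_j / mean(L)`). The prior bounds the log away from
#' minus infinity while keeping the transform scale-invariant.
#'
#' @param x a [MiRNAExperiment-class] or count matrix.
#' @param factors per-sample normalization factors (must be positive);
#'   defaults to all 1.
#' @param priorCount prior count (default 2, the display convention under
#'   which the ubiquitous-expression rule of [ubiquitousMiRNAs()] is
#'   calibrated).
#' @return numeric matrix of log2 CPM values, same dimnames as the counts.
#' @export
logCPMMatrix <- function(x, factors = NULL, priorCount = 2) {
    cnt <- if (is(x, "MiRNAExperiment")) counts(x) else as.matrix(x)
    if (is.null(factors)) factors <- rep(1, ncol(cnt))
    if (any(factors <= 0)) stop("normalization factors must be positive")
    effLib <- colSums(cnt) * factors
    prior <- priorCount * effLib / mean(effLib)
    t(log2((t(cnt) + prior) / (effLib + 2 * prior) * 1e6))
}

#' TMM-normalize a MiRNAExperiment
#'
#' Convenience wrapper: computes [tmmFactors()], stores them in
#' `colData(x)$norm.factor`, and adds a `logcpm` assay from
#' [logCPMMatrix()].
#'
#' @inheritParams tmmFactors
#' @inheritParams logCPMMatrix
#' @return the input object with factors and `logcpm` assay attached.
#' @export
tmmNormalize <- function(x, trimM = 0.30, trimA = 0.05, refSample = NULL,
                         priorCount = 2) {
    stopifnot(is(x, "MiRNAExperiment"))
    f <- tmmFactors(x, trimM = trimM, trimA = trimA, refSample = refSample)
    colData(x)$norm.factor <- unname(f)
    assay(x, "logcpm") <- logCPMMatrix(x, factors = f,
                                       priorCount = priorCount)
    validObject(x)
    x
}

#' Offsets for the NB GLM: log effective library sizes
#'
#' @param x a normalized [MiRNAExperiment-class].
#' @return named numeric vector `log(colSums(counts) * normFactors)`.
#' @export
effectiveLibOffsets <- function(x) {
    log(librarySizes(x) * normFactors(x))
}
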