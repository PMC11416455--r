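## In-code fixtures shared across the suite. Everything is generated
## programmatically; no binary files.

## A tiny MiRNAExperiment with a valid design (one condition cell, n samples).
toyExperiment <- function(counts, genotype = "IC", region = "iPSC",
                          timepoint = "D0") {
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)))
        rownames(counts) <- paste0("miR-", seq_len(nrow(counts)))
    if (is.null(colnames(counts)))
        colnames(counts) <- paste0("s", seq_len(ncol(counts)))
    n <- ncol(counts)
    MiRNAExperiment(counts, data.frame(
        genotype = rep_len(genotype, n), region = rep_len(region, n),
        timepoint = rep_len(timepoint, n), replicate = seq_len(n),
        row.names = colnames(counts)))
}

## Fabricated DETable with given ids and q-values (p = q for simplicity).
fakeDETable <- function(ids, q, lfc = 0) {
    data.frame(mirna_id = ids, log2fc = rep_len(lfc, length(ids)),
               avg_log2cpm = 8, f_stat = 1, df1 = 1, df2 = 10,
               p_value = q, q_value = q)
}

## Six fabricated temporal tables for one region, all null except `sig`.
fakeRegionTables <- function(ids, sig = list()) {
    ctr <- names(temporalContrasts())
    out <- lapply(ctr, function(nm) {
        q <- rep(0.9, length(ids))
        if (!is.null(sig[[nm]])) q[match(sig[[nm]], ids)] <- 0.001
        fakeDETable(ids, q)
    })
    names(out) <- ctr
    out
}

## Straight-line independent re-computation of TMM factors for a two-sample
## matrix (no shared code with the package): explicit M/A/weights, rank
## trimming, precision-weighted mean, geometric-mean rescaling.
oracleTMMTwoSample <- function(cnt, trimM = 0.30, trimA = 0.05) {
    lib <- colSums(cnt)
    f75 <- vapply(1:2, function(j)
        unname(quantile(cnt[, j] / lib[j], 0.75)), numeric(1))
    ref <- which.min(abs(f75 - mean(f75)))
    obsJ <- setdiff(1:2, ref)
    o <- cnt[, obsJ]; r <- cnt[, ref]
    keep <- o > 0 & r > 0
    o <- o[keep]; r <- r[keep]
    M <- log2((o / lib[obsJ]) / (r / lib[ref]))
    A <- 0.5 * log2((o / lib[obsJ]) * (r / lib[ref]))
    v <- (lib[obsJ] - o) / (lib[obsJ] * o) + (lib[ref] - r) / (lib[ref] * r)
    n <- length(M)
    loM <- floor(n * trimM) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trimA) + 1; hiA <- n + 1 - loA
    sel <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    fObs <- if (max(abs(M)) < 1e-6) 1 else 2^(sum(M[sel] / v[sel]) /
                                              sum(1 / v[sel]))
    f <- c(1, 1); f[obsJ] <- fObs
    f <- f / exp(mean(log(f)))
    names(f) <- colnames(cnt)
    f
}

## Adjusted Rand index (independent of mclust, for portability inside tests).
adjRandIndex <- function(a, b) {
    tab <- table(a, b)
    n <- sum(tab)
    sumij <- sum(choose(tab, 2))
    ai <- sum(choose(rowSums(tab), 2)); bj <- sum(choose(colSums(tab), 2))
    expected <- ai * bj / choose(n, 2)
    maxidx <- (ai + bj) / 2
    if (maxidx == expected) return(1)
    (sumij - expected) / (maxidx - expected)
}

## Noisy monotone standardized-profile matrix for clustering tests:
## one row per miRNA over 2 regions x 4 timepoints x `reps` replicates.
plantedProfiles <- function(nUp, nDown, nNull = 0, noiseSD = 0.1,
                            reps = 3, seed = 99) {
    set.seed(seed)
    tIdx <- rep(c(0, 1, 2, 3), each = reps)     # one region's time course
    base <- c(tIdx, tIdx)                       # dorsal + ventral columns
    make <- function(slope, n)
        t(vapply(seq_len(n), function(i)
            slope * base + rnorm(length(base), 0, noiseSD),
            numeric(length(base))))
    m <- rbind(make(1, nUp), make(-1, nDown), make(0, nNull))
    rownames(m) <- paste0("miR-", seq_len(nrow(m)))
    info <- data.frame(
        region = rep(c("dorsal", "ventral"), each = length(tIdx)),
        timepoint = rep(rep(c("D0", "D13", "D40", "D75"), each = reps), 2))
    info$region[info$timepoint == "D0"] <- "iPSC"
    list(m = m, info = info,
         truth = rep(c("up", "down", "null"), c(nUp, nDown, nNull)))
}
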