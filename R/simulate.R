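## Synthetic-data generator: NB count matrices with the two-genotype,
## two-region, four-timepoint organoid design, plus matched annotation,
## target-map and pathway resources with ground-truth labels.

#' Derive a reproducible sub-seed from a global seed
#'
#' All stochastic operations of the generator and pipeline derive their
#' seeds deterministically from one global integer seed, keeping every
#' fixture bit-reproducible. Results stay below 2^31 - 1.
#'
#' @param seed global integer seed.
#' @param salt integer stream identifier.
#' @return an integer seed.
#' @export
deriveSeed <- function(seed, salt) {
    as.integer((as.double(seed) %% 2147483647 * 69069 + salt * 2654435) %%
               2147483647)
}

#' Enumerate the condition cells of the organoid design
#'
#' The design nests timepoints in regions: the iPSC baseline exists only at
#' D0 and the organoid timepoints D13/D40/D75 only in the dorsal and
#' ventral regions, giving 7 region/timepoint cells per genotype (14 in
#' total). The single iPSC D0 cell per genotype is shared by both regional
#' analyses.
#'
#' @return data.frame with columns `genotype`, `region`, `timepoint`,
#'   `condition` (unique label), one row per cell.
#' @export
conditionCells <- function() {
    rt <- rbind(data.frame(region = "iPSC", timepoint = "D0"),
                expand.grid(region = c("dorsal", "ventral"),
                            timepoint = c("D13", "D40", "D75"),
                            stringsAsFactors = FALSE))
    out <- merge(data.frame(genotype = GENOTYPES), rt)
    out <- out[order(out$genotype, match(out$region, REGIONS),
                     match(out$timepoint, TIMEPOINTS)), ]
    out$condition <- paste(out$genotype, out$region, out$timepoint, sep = "_")
    rownames(out) <- NULL
    out
}

.classVector <- function(design, effects) {
    n <- design@nMirnas
    ns <- c(genotype_elevated = effects@nGenotypeCluster,
            increasing = effects@nIncreasing,
            decreasing = effects@nDecreasing,
            ubiquitous = effects@nUbiquitous)
    if (sum(ns) > n)
        stop("planted class counts (", sum(ns),
             ") exceed nMirnas (", n, ")")
    rep(c(names(ns), "null"), c(ns, n - sum(ns)))
}

#' Simulate negative-binomial miRNA counts for the organoid design
#'
#' Draws counts `NB(mean = librarySize x relative abundance,
#' dispersion = nbDispersion)` for every sample of the 14-cell design.
#' Baseline abundances are log-normal (miRNA libraries are highly skewed);
#' planted classes modify the per-condition log2 abundance: monotone
#' increasing/decreasing classes change by a fixed log2 step per timepoint,
#' the genotype-elevated class (laid out contiguously so it can form a
#' genomic cluster, see [simulateAnnotation()]) gains `genotypeLog2FC` in
#' every RTT sample, the ubiquitous class is pinned at a true log2 CPM of
#' `ubiquitousLog2CPM` in every condition, and a fraction of null miRNAs
#' receives a dorsal-specific abundance shift to exercise the TMM
#' composition correction. Abundances are renormalized to proportions
#' within each condition, so library size and composition are decoupled.
#' With `nbDispersion = 0` the counts are Poisson.
#'
#' @param design a [DesignSpec-class].
#' @param effects an [EffectSpec-class].
#' @param seed integer seed; identical seed and specs reproduce identical
#'   output.
#' @return list with `experiment` (a [MiRNAExperiment-class]) and `truth`:
#'   `labels` (data.frame: `mirna_id`, `class`, `composition_biased`),
#'   `trueLog2CPM` (miRNA x condition matrix of true log2 CPM),
#'   `trueLibSizes` and `trueFactors` (the planted per-sample scaling, as
#'   geometric-mean-1 TMM-style factors).
#' @export
simulateCounts <- function(design, effects, seed = 1L) {
    stopifnot(is(design, "DesignSpec"), is(effects, "EffectSpec"))
    validObject(design); validObject(effects)
    cells <- conditionCells()
    nCell <- nrow(cells)
    reps <- design@replicates
    G <- design@nMirnas
    cls <- .classVector(design, effects)
    ids <- sprintf("miR-%04d", seq_len(G))

    set.seed(deriveSeed(seed, 1L))
    base <- stats::rnorm(G, effects@baselineLog2Mean, effects@baselineLog2SD)

    nullIdx <- which(cls == "null")
    nBias <- floor(effects@compositionBiasFraction * length(nullIdx))
    biasIdx <- if (nBias > 0) nullIdx[seq_len(nBias)] else integer(0)

    tIdx <- match(cells$timepoint, TIMEPOINTS) - 1L  # 0..3
    logAb <- matrix(rep(base, nCell), nrow = G,
                    dimnames = list(ids, cells$condition))
    inc <- cls == "increasing"; dec <- cls == "decreasing"
    logAb[inc, ] <- logAb[inc, ] +
        outer(rep(effects@log2StepIncreasing, sum(inc)), tIdx)
    logAb[dec, ] <- logAb[dec, ] -
        outer(rep(effects@log2StepDecreasing, sum(dec)), tIdx)
    ge <- cls == "genotype_elevated"
    rtt <- cells$genotype == "RTT"
    logAb[ge, rtt] <- logAb[ge, rtt] + effects@genotypeLog2FC
    dorsal <- cells$region == "dorsal"
    logAb[biasIdx, dorsal] <- logAb[biasIdx, dorsal] +
        effects@compositionBiasLog2FC

    ## abundance -> per-condition relative abundance; ubiquitous miRNAs get
    ## a constant weight anchored to the mean non-ubiquitous composition so
    ## their normalized CPM stays at the target level in every condition
    w <- 2^logAb
    ubi <- cls == "ubiquitous"
    fUbi <- 2^effects@ubiquitousLog2CPM / 1e6
    if (sum(ubi) * fUbi >= 1)
        stop("ubiquitous class would exceed the whole library")
    if (any(ubi)) {
        sBase <- mean(colSums(w[!ubi, , drop = FALSE]))
        w[ubi, ] <- fUbi / (1 - sum(ubi) * fUbi) * sBase
    }
    theta <- sweep(w, 2, colSums(w), "/")

    ## samples: library sizes log-normal with the requested mean and CV
    samples <- cells[rep(seq_len(nCell), each = reps), ]
    samples$replicate <- rep(seq_len(reps), nCell)
    samples$sample_id <- paste0(samples$condition, "_r", samples$replicate)
    nS <- nrow(samples)
    set.seed(deriveSeed(seed, 2L))
    if (design@libSizeCV > 0) {
        sdl <- sqrt(log(1 + design@libSizeCV^2))
        lib <- stats::rlnorm(nS, log(design@meanLibSize) - sdl^2 / 2, sdl)
    } else lib <- rep(design@meanLibSize, nS)

    mu <- theta[, match(samples$condition, cells$condition), drop = FALSE]
    mu <- sweep(mu, 2, lib, "*")
    set.seed(deriveSeed(seed, 3L))
    cnt <- if (design@nbDispersion > 0)
        matrix(stats::rnbinom(G * nS, mu = mu, size = 1 / design@nbDispersion),
               nrow = G)
    else matrix(stats::rpois(G * nS, mu), nrow = G)
    dimnames(cnt) <- list(ids, samples$sample_id)

    sd <- data.frame(genotype = samples$genotype, region = samples$region,
                     timepoint = samples$timepoint,
                     replicate = samples$replicate,
                     row.names = samples$sample_id)
    exper <- MiRNAExperiment(cnt, sd)

    ## planted TMM-style factor: corrects realized depth and composition so
    ## that null miRNAs align across samples (geometric mean 1)
    sCond <- colSums(w)[match(samples$condition, cells$condition)]
    colSum <- pmax(colSums(cnt), 1)
    f <- lib / (colSum * sCond)
    f <- f / exp(mean(log(f)))
    labels <- data.frame(mirna_id = ids, class = cls,
                         composition_biased = seq_len(G) %in% biasIdx)
    list(experiment = exper,
         truth = list(labels = labels,
                      trueLog2CPM = log2(theta * 1e6),
                      trueLibSizes = stats::setNames(lib, samples$sample_id),
                      trueFactors = stats::setNames(f, samples$sample_id),
                      conditions = cells))
}

#' Simulate a genomic annotation with a planted miRNA cluster
#'
#' Places the genotype-elevated miRNAs on adjacent, non-overlapping
#' intervals inside `clusterLocus` (equally spaced, sorted by miRNA index)
#' under a shared `cluster_id`, and scatters all other miRNAs across the
#' remaining autosomes without a cluster label.
#'
#' @param labels truth-label data.frame from [simulateCounts()] (`$truth$labels`).
#' @param clusterLocus length-1 `GRanges` hosting the cluster; the default
#'   is a chr14q32-style 200 kb window echoing the C14MC locus.
#' @param clusterId label for the planted cluster (default `"C14MC"`).
#' @param seed integer seed.
#' @param featureWidth interval width in bp (default 80, a typical miRNA
#'   precursor span).
#' @return `GRanges` in truth row order with metadata columns `mirna_id`
#'   and `cluster_id` (NA outside the cluster).
#' @export
simulateAnnotation <- function(labels,
                               clusterLocus = GenomicRanges::GRanges(
                                   "chr14", IRanges::IRanges(100900001,
                                                             101100000)),
                               clusterId = "C14MC", seed = 1L,
                               featureWidth = 80L) {
    stopifnot(length(clusterLocus) == 1)
    ids <- labels$mirna_id
    inCl <- labels$class == "genotype_elevated"
    nCl <- sum(inCl)
    chrom <- character(length(ids)); st <- integer(length(ids))
    strand <- rep("+", length(ids))
    if (nCl > 0) {
        span <- width(clusterLocus)
        step <- floor(span / nCl)
        if (step < featureWidth)
            stop("cluster locus too small for ", nCl, " members of width ",
                 featureWidth)
        st[inCl] <- start(clusterLocus) + (seq_len(nCl) - 1L) * step
        chrom[inCl] <- as.character(seqnames(clusterLocus))
    }
    other <- which(!inCl)
    set.seed(deriveSeed(seed, 11L))
    pool <- paste0("chr", setdiff(1:22, 14))
    chrom[other] <- sample(pool, length(other), replace = TRUE)
    st[other] <- sample.int(1e8, length(other), replace = TRUE)
    strand[other] <- sample(c("+", "-"), length(other), replace = TRUE)
    gr <- GenomicRanges::GRanges(chrom,
                                 IRanges::IRanges(st,
                                                  width = featureWidth),
                                 strand = strand)
    S4Vectors::mcols(gr)$mirna_id <- ids
    S4Vectors::mcols(gr)$cluster_id <- ifelse(inCl, clusterId, NA_character_)
    names(gr) <- ids
    gr
}

.geneIds <- function(nGenes) sprintf("G%05d", seq_len(nGenes))

#' Simulate a miRNA-to-target-gene map
#'
#' Every miRNA receives a Poisson-sized target-gene set drawn from a
#' universe of `nGenes` genes; miRNAs of `enrichedClass` draw a fraction
#' `enrichedPathwayFraction` of their targets from a designated gene block
#' (by default the first `nEnrichedGenes` genes, the set that
#' [simulatePathways()] plants as its first pathway), so pathway-enrichment
#' recovery is testable. Target-set sizes of 0 (empty sets) occur naturally.
#'
#' @param labels truth-label data.frame from [simulateCounts()].
#' @param nGenes size of the gene universe.
#' @param meanTargets Poisson mean of the per-miRNA target count
#'   (default 25).
#' @param enrichedPathwayFraction fraction of an enriched miRNA's targets
#'   drawn from the designated gene block (default 0.8).
#' @param seed integer seed.
#' @param enrichedClass truth class whose targets are enriched (default
#'   `"genotype_elevated"`).
#' @param nEnrichedGenes size of the designated block (default 100).
#' @return a [MiRNATargets-class] whose pool is all labelled miRNAs.
#' @export
simulateTargetMap <- function(labels, nGenes = 2000L, meanTargets = 25,
                              enrichedPathwayFraction = 0.8, seed = 1L,
                              enrichedClass = "genotype_elevated",
                              nEnrichedGenes = 100L) {
    genes <- .geneIds(nGenes)
    if (nGenes <= meanTargets)
        stop("nGenes must exceed the mean target-set size")
    enr <- genes[seq_len(min(nEnrichedGenes, nGenes))]
    rest <- setdiff(genes, enr)
    set.seed(deriveSeed(seed, 21L))
    map <- lapply(seq_len(nrow(labels)), function(i) {
        nT <- stats::rpois(1, meanTargets)
        nT <- min(nT, nGenes)
        if (nT == 0) return(character(0))
        if (labels$class[i] == enrichedClass) {
            nE <- min(round(enrichedPathwayFraction * nT), length(enr))
            c(sample(enr, nE), sample(rest, nT - nE))
        } else sample(genes, nT)
    })
    names(map) <- labels$mirna_id
    MiRNATargets(map, pool = labels$mirna_id)
}

#' Simulate a pathway collection
#'
#' Draws `nPathways` random gene sets over a universe of `nGenes` genes,
#' with Poisson sizes around `meanGenesPerPathway`. Named sets in
#' `fixedSets` are placed first unchanged, which is how the designated
#' enriched gene block of [simulateTargetMap()] becomes a plantable
#' pathway.
#'
#' @param nPathways number of random pathways.
#' @param meanGenesPerPathway Poisson mean pathway size (default 50).
#' @param nGenes gene-universe size (must cover the largest pathway).
#' @param seed integer seed.
#' @param fixedSets optional named list of gene sets to include verbatim.
#' @return a [PathwayCollection-class] whose universe is all `nGenes`
#'   genes.
#' @export
simulatePathways <- function(nPathways = 50L, meanGenesPerPathway = 50,
                             nGenes = 2000L, seed = 1L, fixedSets = list()) {
    genes <- .geneIds(nGenes)
    set.seed(deriveSeed(seed, 31L))
    sets <- lapply(seq_len(nPathways), function(i) {
        sz <- max(1L, min(stats::rpois(1, meanGenesPerPathway), nGenes))
        sample(genes, sz)
    })
    names(sets) <- sprintf("WP%04d", seq_len(nPathways))
    if (length(fixedSets)) {
        stopifnot(!is.null(names(fixedSets)))
        bad <- setdiff(unlist(fixedSets), genes)
        if (length(bad)) stop("fixedSets contain genes outside the universe")
        sets <- c(fixedSets, sets)
    }
    PathwayCollection(sets, universe = genes)
}
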