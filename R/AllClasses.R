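#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames assay<- colData colData<- rowData
#' @importFrom GenomicRanges GRanges start end width seqnames strand
#' @importFrom IRanges IRanges
NULL

GENOTYPES  <- c("IC", "RTT")
REGIONS    <- c("iPSC", "dorsal", "ventral")
TIMEPOINTS <- c("D0", "D13", "D40", "D75")

#' Container for miRNA-by-sample counts with organoid design metadata
#'
#' `MiRNAExperiment` extends [SummarizedExperiment::SummarizedExperiment] and
#' holds a non-negative integer `counts` assay together with the per-sample
#' design covariates of the organoid study: genotype (`IC` isogenic control or
#' `RTT` MeCP2-mutant), region (`iPSC`, `dorsal`, `ventral`), timepoint
#' (`D0`, `D13`, `D40`, `D75`) and replicate number. After
#' [tmmNormalize()] it additionally carries a `logcpm` assay and the TMM
#' scaling factor of each sample in `colData(x)$norm.factor`.
#'
#' Validity enforces the design vocabulary, uniqueness of miRNA and sample
#' identifiers, non-negative counts and the study's region/timepoint nesting:
#' `D0` occurs only in `iPSC` samples and the organoid timepoints
#' `D13`/`D40`/`D75` only in `dorsal` or `ventral` samples.
#'
#' @aliases MiRNAExperiment
#' @exportClass MiRNAExperiment
setClass("MiRNAExperiment", contains = "SummarizedExperiment")

setValidity("MiRNAExperiment", function(object) {
    msg <- NULL
    if (!("counts" %in% assayNames(object)))
        msg <- c(msg, "assay 'counts' is required")
    else {
        cnt <- assay(object, "counts")
        if (any(!is.finite(cnt)) || any(cnt < 0))
            msg <- c(msg, "counts must be finite and non-negative")
        if (any(abs(cnt - round(cnt)) > 1e-8))
            msg <- c(msg, "counts must be integers")
    }
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicate miRNA ids")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicate sample ids")
    cd <- colData(object)
    need <- c("genotype", "region", "timepoint", "replicate")
    miss <- setdiff(need, colnames(cd))
    if (length(miss))
        msg <- c(msg, paste0("colData lacks: ", paste(miss, collapse = ", ")))
    else {
        if (!all(cd$genotype %in% GENOTYPES))
            msg <- c(msg, "genotype must be IC or RTT")
        if (!all(cd$region %in% REGIONS))
            msg <- c(msg, "region must be iPSC, dorsal or ventral")
        if (!all(cd$timepoint %in% TIMEPOINTS))
            msg <- c(msg, "timepoint must be one of D0, D13, D40, D75")
        bad <- xor(cd$timepoint == "D0", cd$region == "iPSC")
        if (any(bad))
            msg <- c(msg, "timepoint D0 must coincide exactly with region iPSC")
        if (!all(cd$replicate >= 1))
            msg <- c(msg, "replicate must be a positive integer")
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct a MiRNAExperiment
#'
#' @param counts non-negative integer matrix, miRNAs in rows (rownames are
#'   miRNA ids), samples in columns (colnames are sample ids).
#' @param sampleData data.frame (or DataFrame) with one row per sample and
#'   columns `genotype`, `region`, `timepoint`, `replicate`.
#' @return a [MiRNAExperiment-class] object.
#' @examples
#' cnt <- matrix(rpois(40, 50), nrow = 10,
#'               dimnames = list(paste0("miR-", 1:10), paste0("s", 1:4)))
#' sd <- data.frame(genotype = "IC", region = "iPSC", timepoint = "D0",
#'                  replicate = 1:4, row.names = paste0("s", 1:4))
#' MiRNAExperiment(cnt, sd)
#' @export
MiRNAExperiment <- function(counts, sampleData) {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "double"
    sampleData <- as(sampleData, "DataFrame")
    se <- SummarizedExperiment(assays = list(counts = counts),
                               colData = sampleData)
    new("MiRNAExperiment", se)
}

setMethod("show", "MiRNAExperiment", function(object) {
    callNextMethod()
    cd <- colData(object)
    cat("design:", length(unique(paste(cd$genotype, cd$region, cd$timepoint))),
        "condition cells;",
        sum(cd$genotype == "IC"), "IC /", sum(cd$genotype == "RTT"),
        "RTT samples\n")
    if ("norm.factor" %in% colnames(cd))
        cat("TMM-normalized (assay 'logcpm' present)\n")
})

#' @describeIn MiRNAExperiment raw count matrix accessor.
#' @param x,object a `MiRNAExperiment`.
#' @export
counts <- function(x) assay(x, "counts")

#' @describeIn MiRNAExperiment log2 CPM assay (after [tmmNormalize()]).
#' @export
logCPM <- function(x) {
    if (!("logcpm" %in% assayNames(x)))
        stop("no 'logcpm' assay; run tmmNormalize() first")
    assay(x, "logcpm")
}

#' @describeIn MiRNAExperiment per-sample TMM factors (after
#'   [tmmNormalize()]).
#' @export
normFactors <- function(x) {
    if (!("norm.factor" %in% colnames(colData(x))))
        stop("no norm factors; run tmmNormalize() first")
    stats::setNames(colData(x)$norm.factor, colnames(x))
}

#' @describeIn MiRNAExperiment per-sample library sizes (column sums).
#' @export
librarySizes <- function(x) colSums(counts(x))

#' Design specification of the simulated organoid study
#'
#' Encodes the sampling frame the generator emulates: two genotypes, an
#' iPSC baseline plus dorsal and ventral organoids at three timepoints,
#' a fixed replicate count per condition cell, and the sequencing-depth and
#' overdispersion regime. The default design yields 14 condition cells
#' (iPSC D0 x 2 genotypes + 2 regions x 3 timepoints x 2 genotypes) and,
#' with triplicates, 42 samples.
#'
#' @slot replicates replicates per condition cell (default 3).
#' @slot nMirnas number of simulated miRNAs.
#' @slot meanLibSize expected library size in reads (default 1e6).
#' @slot libSizeCV coefficient of variation of the log-normal library sizes.
#' @slot nbDispersion negative-binomial dispersion (0 gives Poisson counts).
#' @exportClass DesignSpec
setClass("DesignSpec", representation(
    replicates = "integer", nMirnas = "integer",
    meanLibSize = "numeric", libSizeCV = "numeric", nbDispersion = "numeric"))

setValidity("DesignSpec", function(object) {
    msg <- NULL
    if (object@replicates < 1L) msg <- c(msg, "replicates must be >= 1")
    if (object@nMirnas < 1L) msg <- c(msg, "nMirnas must be >= 1")
    if (object@meanLibSize <= 0) msg <- c(msg, "meanLibSize must be > 0")
    if (object@libSizeCV < 0) msg <- c(msg, "libSizeCV must be >= 0")
    if (object@nbDispersion < 0) msg <- c(msg, "nbDispersion must be >= 0")
    if (is.null(msg)) TRUE else msg
})

#' @rdname DesignSpec-class
#' @param replicates,nMirnas,meanLibSize,libSizeCV,nbDispersion see slots.
#' @export
DesignSpec <- function(replicates = 3L, nMirnas = 600L, meanLibSize = 1e6,
                       libSizeCV = 0.2, nbDispersion = 0.1) {
    new("DesignSpec", replicates = as.integer(replicates),
        nMirnas = as.integer(nMirnas), meanLibSize = meanLibSize,
        libSizeCV = libSizeCV, nbDispersion = nbDispersion)
}

setMethod("show", "DesignSpec", function(object) {
    cat("DesignSpec: 14 condition cells x", object@replicates,
        "replicates =", 14L * object@replicates, "samples;",
        object@nMirnas, "miRNAs\n")
    cat("  mean library size", object@meanLibSize, " CV", object@libSizeCV,
        " NB dispersion", object@nbDispersion, "\n")
})

#' Planted effect structure for the synthetic generator
#'
#' Describes which miRNA classes are planted and at what effect sizes:
#' monotone increasing/decreasing temporal classes (per-timepoint log2
#' increments), a genomically clustered genotype-elevated class (log2
#' fold-change in RTT), a ubiquitously high class, and a fraction of
#' composition-biased miRNAs that stress the TMM normalization. All
#' remaining miRNAs are null.
#'
#' @slot nIncreasing,nDecreasing sizes of the monotone temporal classes.
#' @slot nGenotypeCluster size of the genotype-elevated genomic cluster.
#' @slot nUbiquitous size of the ubiquitously expressed class.
#' @slot log2StepIncreasing,log2StepDecreasing per-timepoint log2 increments
#'   (the decreasing step is applied with negative sign).
#' @slot genotypeLog2FC RTT-vs-IC log2 fold-change of the clustered class.
#' @slot baselineLog2Mean,baselineLog2SD parameters of the log-normal
#'   baseline relative abundances (log2 scale).
#' @slot ubiquitousLog2CPM target true log2 CPM of the ubiquitous class.
#' @slot compositionBiasFraction fraction of null miRNAs given a
#'   dorsal-specific abundance shift.
#' @slot compositionBiasLog2FC size of that shift.
#' @exportClass EffectSpec
setClass("EffectSpec", representation(
    nIncreasing = "integer", nDecreasing = "integer",
    nGenotypeCluster = "integer", nUbiquitous = "integer",
    log2StepIncreasing = "numeric", log2StepDecreasing = "numeric",
    genotypeLog2FC = "numeric",
    baselineLog2Mean = "numeric", baselineLog2SD = "numeric",
    ubiquitousLog2CPM = "numeric",
    compositionBiasFraction = "numeric", compositionBiasLog2FC = "numeric"))

setValidity("EffectSpec", function(object) {
    msg <- NULL
    ns <- c(object@nIncreasing, object@nDecreasing, object@nGenotypeCluster,
            object@nUbiquitous)
    if (any(ns < 0L)) msg <- c(msg, "class counts must be >= 0")
    if (object@compositionBiasFraction < 0 ||
        object@compositionBiasFraction > 1)
        msg <- c(msg, "compositionBiasFraction must lie in [0, 1]")
    if (object@baselineLog2SD < 0) msg <- c(msg, "baselineLog2SD must be >= 0")
    if (is.null(msg)) TRUE else msg
})

#' @rdname EffectSpec-class
#' @param nIncreasing,nDecreasing,nGenotypeCluster,nUbiquitous,
#'   log2StepIncreasing,log2StepDecreasing,genotypeLog2FC,baselineLog2Mean,
#'   baselineLog2SD,ubiquitousLog2CPM,compositionBiasFraction,
#'   compositionBiasLog2FC see slots.
#' @export
EffectSpec <- function(nIncreasing = 10L, nDecreasing = 10L,
                       nGenotypeCluster = 50L, nUbiquitous = 10L,
                       log2StepIncreasing = 1, log2StepDecreasing = 1,
                       genotypeLog2FC = 1.0,
                       baselineLog2Mean = 6, baselineLog2SD = 2,
                       ubiquitousLog2CPM = 13,
                       compositionBiasFraction = 0.05,
                       compositionBiasLog2FC = 2) {
    new("EffectSpec", nIncreasing = as.integer(nIncreasing),
        nDecreasing = as.integer(nDecreasing),
        nGenotypeCluster = as.integer(nGenotypeCluster),
        nUbiquitous = as.integer(nUbiquitous),
        log2StepIncreasing = log2StepIncreasing,
        log2StepDecreasing = log2StepDecreasing,
        genotypeLog2FC = genotypeLog2FC,
        baselineLog2Mean = baselineLog2Mean, baselineLog2SD = baselineLog2SD,
        ubiquitousLog2CPM = ubiquitousLog2CPM,
        compositionBiasFraction = compositionBiasFraction,
        compositionBiasLog2FC = compositionBiasLog2FC)
}

setMethod("show", "EffectSpec", function(object) {
    cat("EffectSpec: planted classes",
        sprintf("increasing=%d decreasing=%d genotype_cluster=%d ubiquitous=%d",
                object@nIncreasing, object@nDecreasing,
                object@nGenotypeCluster, object@nUbiquitous), "\n")
})

#' miRNA-to-target-gene map
#'
#' Holds the mapping from each miRNA to its set of target genes, together
#' with the miRNA sampling pool used by the permutation null (all measured
#' miRNAs, including those with empty target sets).
#'
#' @slot map named list of character vectors (gene ids per miRNA).
#' @slot pool character vector of all miRNAs eligible for permutation draws.
#' @exportClass MiRNATargets
setClass("MiRNATargets",
         representation(map = "list", pool = "character"))

setValidity("MiRNATargets", function(object) {
    msg <- NULL
    if (is.null(names(object@map)) || anyDuplicated(names(object@map)))
        msg <- c(msg, "map must be a uniquely named list")
    if (!all(names(object@map) %in% object@pool))
        msg <- c(msg, "pool must contain every mapped miRNA")
    if (is.null(msg)) TRUE else msg
})

#' @rdname MiRNATargets-class
#' @param map named list mapping miRNA id -> character vector of gene ids.
#' @param pool optional sampling pool; defaults to the mapped miRNAs.
#' @export
MiRNATargets <- function(map, pool = names(map)) {
    map <- lapply(map, function(g) unique(as.character(g)))
    new("MiRNATargets", map = map, pool = unique(as.character(pool)))
}

setMethod("show", "MiRNATargets", function(object) {
    sizes <- lengths(object@map)
    cat("MiRNATargets:", length(object@map), "mapped miRNAs, pool of",
        length(object@pool), "\n")
    cat("  target-set sizes: median", stats::median(sizes), " max", max(sizes),
        " empty", sum(sizes == 0), "\n")
})

#' @describeIn MiRNATargets-class target gene sets (named list).
#' @param x,object a `MiRNATargets`.
#' @export
targetSets <- function(x) x@map

#' @describeIn MiRNATargets-class miRNA sampling pool.
#' @export
mirnaPool <- function(x) x@pool

#' Named pathway gene sets over a gene universe
#'
#' @slot sets named list of character vectors (member genes per pathway).
#' @slot description per-pathway description strings (GMT column 2).
#' @slot universe genes eligible for over-representation testing. Defaults
#'   to the union of all pathway members.
#' @exportClass PathwayCollection
setClass("PathwayCollection",
         representation(sets = "list", description = "character",
                        universe = "character"))

setValidity("PathwayCollection", function(object) {
    msg <- NULL
    if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
        msg <- c(msg, "pathway ids must be unique and named")
    if (length(object@description) != length(object@sets))
        msg <- c(msg, "one description per pathway required")
    if (!all(unlist(object@sets) %in% object@universe))
        msg <- c(msg, "every pathway gene must lie in the universe")
    if (is.null(msg)) TRUE else msg
})

#' @rdname PathwayCollection-class
#' @param sets named list of gene-id vectors.
#' @param description optional character vector, one per pathway.
#' @param universe optional gene universe (default: union of all sets).
#' @export
PathwayCollection <- function(sets, description = NULL, universe = NULL) {
    sets <- lapply(sets, function(g) unique(as.character(g)))
    if (is.null(description)) description <- rep("na", length(sets))
    if (is.null(universe)) universe <- unique(unlist(sets, use.names = FALSE))
    if (is.null(universe)) universe <- character(0)
    new("PathwayCollection", sets = sets,
        description = as.character(description),
        universe = unique(as.character(universe)))
}

setMethod("show", "PathwayCollection", function(object) {
    cat("PathwayCollection:", length(object@sets), "pathways over a universe of",
        length(object@universe), "genes\n")
    if (length(object@sets))
        cat("  sizes: ", paste(range(lengths(object@sets)), collapse = " - "),
            "\n")
})

#' @describeIn PathwayCollection-class pathway gene sets (named list).
#' @param x,object a `PathwayCollection`.
#' @export
pathwaySets <- function(x) x@sets

#' @describeIn PathwayCollection-class the gene universe.
#' @export
geneUniverse <- function(x) x@universe

#' Dispersion estimates for the quasi-likelihood pipeline
#'
#' Returned by [estimateDispersions()]: the abundance-dependent trended NB
#' dispersion per miRNA, the raw quasi-dispersions (residual deviance over
#' residual df at the trended NB dispersion), and their empirical-Bayes
#' squeezed counterparts with the estimated prior df.
#'
#' @slot trended per-miRNA trended NB dispersion.
#' @slot aveLogCPM per-miRNA average log2 CPM used for the trend.
#' @slot quasi raw per-miRNA quasi-dispersions.
#' @slot quasiSqueezed squeezed quasi-dispersions.
#' @slot priorDF estimated prior degrees of freedom (may be `Inf`).
#' @slot residDF residual degrees of freedom of the fit.
#' @exportClass DispersionEstimates
setClass("DispersionEstimates", representation(
    trended = "numeric", aveLogCPM = "numeric", quasi = "numeric",
    quasiSqueezed = "numeric", priorDF = "numeric", residDF = "numeric"))

setMethod("show", "DispersionEstimates", function(object) {
    cat("DispersionEstimates for", length(object@trended), "miRNAs\n")
    cat("  trended NB dispersion: median",
        signif(stats::median(object@trended), 3), "\n")
    cat("  quasi-dispersion prior df:", signif(object@priorDF, 4),
        "; residual df:", object@residDF, "\n")
})
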