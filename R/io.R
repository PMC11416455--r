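## Readers, writers and the end-to-end pipeline driver. All tabular files
## are UTF-8 TSV with stable headers; missing values are written as ".".

.configError <- function(...) stop(errorCondition(paste0(...),
    class = c("ev_config_error", "error", "condition")))
.formatError <- function(...) stop(errorCondition(paste0(...),
    class = c("ev_format_error", "error", "condition")))

.writeTSV <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = ".")
}

.writeMatrixTSV <- function(m, path, idCol = "mirna_id") {
    df <- data.frame(rownames(m), m, check.names = FALSE)
    colnames(df)[1] <- idCol
    .writeTSV(df, path)
}

#' Read a count matrix and sample sheet
#'
#' The counts TSV has a header of sample ids and miRNA ids in its first
#' column; the sample sheet TSV has columns `sample_id`, `genotype`,
#' `region`, `timepoint`, `replicate`. Cells are validated as non-negative
#' integers; duplicate ids and ragged rows are format errors reporting the
#' offending line.
#'
#' @param countsPath,samplesPath input TSV paths.
#' @return a [MiRNAExperiment-class].
#' @export
readCounts <- function(countsPath, samplesPath) {
    if (!file.exists(countsPath)) .configError("missing file: ", countsPath)
    if (!file.exists(samplesPath)) .configError("missing file: ", samplesPath)
    lines <- readLines(countsPath)
    if (length(lines) < 2) .formatError(countsPath, ": empty count matrix")
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nc <- lengths(parts)
    if (any(nc != nc[1]))
        .formatError(countsPath, ": ragged row at line ",
                     which(nc != nc[1])[1])
    hdr <- parts[[1]][-1]
    ids <- vapply(parts[-1], `[`, character(1), 1)
    if (anyDuplicated(ids))
        .formatError(countsPath, ": duplicate miRNA id at line ",
                     which(duplicated(ids))[1] + 1)
    if (anyDuplicated(hdr)) .formatError(countsPath, ": duplicate sample ids")
    cnt <- matrix(NA_real_, length(ids), length(hdr),
                  dimnames = list(ids, hdr))
    for (i in seq_along(ids)) {
        v <- suppressWarnings(as.numeric(parts[[i + 1]][-1]))
        if (any(is.na(v)) || any(v < 0) || any(v != round(v)))
            .formatError(countsPath,
                         ": non-negative integer expected at line ", i + 1)
        cnt[i, ] <- v
    }
    ss <- utils::read.delim(samplesPath, stringsAsFactors = FALSE)
    need <- c("sample_id", "genotype", "region", "timepoint", "replicate")
    if (!all(need %in% colnames(ss)))
        .formatError(samplesPath, ": columns required: ",
                     paste(need, collapse = ", "))
    if (!setequal(ss$sample_id, hdr))
        .formatError("sample sheet and count columns disagree")
    ss <- ss[match(hdr, ss$sample_id), ]
    MiRNAExperiment(cnt, data.frame(ss[, setdiff(need, "sample_id")],
                                    row.names = ss$sample_id))
}

#' @rdname readCounts
#' @param x a [MiRNAExperiment-class] to write.
#' @export
writeCounts <- function(x, countsPath, samplesPath) {
    .writeMatrixTSV(counts(x), countsPath)
    cd <- colData(x)
    .writeTSV(data.frame(sample_id = colnames(x), genotype = cd$genotype,
                         region = cd$region, timepoint = cd$timepoint,
                         replicate = cd$replicate), samplesPath)
    invisible(c(countsPath, samplesPath))
}

#' Read or write a genomic miRNA annotation
#'
#' The on-disk format is BED6 (0-based half-open starts; the in-memory
#' `GRanges` follows the 1-based Bioconductor convention, so a BED line
#' `chr14 100 200` becomes a width-100 range at 101-200) plus an optional
#' two-column cluster-membership TSV (`mirna_id`, `cluster_id`).
#'
#' @param bedPath BED6 file path.
#' @param clusterPath optional cluster TSV path.
#' @return `GRanges` with `mirna_id` and `cluster_id` metadata columns.
#' @export
readAnnotation <- function(bedPath, clusterPath = NULL) {
    if (!file.exists(bedPath)) .configError("missing file: ", bedPath)
    gr <- rtracklayer::import(bedPath, format = "BED")
    if (!all(as.character(strand(gr)) %in% c("+", "-")))
        .formatError(bedPath, ": strand must be + or -")
    mc <- S4Vectors::mcols(gr)
    mc$mirna_id <- mc$name
    mc$cluster_id <- NA_character_
    if (!is.null(clusterPath)) {
        cl <- utils::read.delim(clusterPath, stringsAsFactors = FALSE)
        unknown <- setdiff(cl$mirna_id, mc$mirna_id)
        if (length(unknown))
            warning("cluster file names unknown miRNA(s): ",
                    paste(unknown, collapse = ", "))
        mc$cluster_id <- cl$cluster_id[match(mc$mirna_id, cl$mirna_id)]
    }
    S4Vectors::mcols(gr) <- mc[, c("mirna_id", "cluster_id")]
    names(gr) <- mc$mirna_id
    gr
}

#' @rdname readAnnotation
#' @param annotation `GRanges` with `mirna_id`/`cluster_id` columns.
#' @export
writeAnnotation <- function(annotation, bedPath, clusterPath = NULL) {
    mc <- S4Vectors::mcols(annotation)
    bed <- annotation
    S4Vectors::mcols(bed) <- S4Vectors::DataFrame(name = mc$mirna_id,
                                                  score = 0)
    rtracklayer::export(bed, bedPath, format = "BED")
    if (!is.null(clusterPath)) {
        keep <- !is.na(mc$cluster_id)
        .writeTSV(data.frame(mirna_id = mc$mirna_id[keep],
                             cluster_id = mc$cluster_id[keep]), clusterPath)
    }
    invisible(bedPath)
}

#' Read or write a miRNA-target interaction table
#'
#' Two tab-separated columns (`mirna_id`, `gene_id`), one pair per line;
#' a header line is optional and detected by its first field. Repeated
#' pairs collapse to a single membership.
#'
#' @param path TSV path.
#' @param pool optional miRNA sampling pool; defaults to the mapped
#'   miRNAs.
#' @return a [MiRNATargets-class].
#' @export
readTargets <- function(path, pool = NULL) {
    if (!file.exists(path)) .configError("missing file: ", path)
    df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                            col.names = c("mirna_id", "gene_id"))
    if (nrow(df) && tolower(df$mirna_id[1]) %in% c("mirna_id", "mirna"))
        df <- df[-1, , drop = FALSE]
    map <- lapply(split(df$gene_id, df$mirna_id), unique)
    if (is.null(pool)) pool <- names(map)
    MiRNATargets(map, pool = union(pool, names(map)))
}

#' @rdname readTargets
#' @param targets a [MiRNATargets-class] to write.
#' @export
writeTargets <- function(targets, path) {
    m <- targetSets(targets)
    df <- data.frame(mirna_id = rep(names(m), lengths(m)),
                     gene_id = unlist(m, use.names = FALSE))
    .writeTSV(df, path)
    invisible(path)
}

#' Read or write pathway gene sets in GMT format
#'
#' GMT lines are tab-separated: set name, description, then member genes.
#' Lines with fewer than three fields are rejected; duplicate genes within
#' a set are removed with a warning.
#'
#' @param path GMT file path.
#' @param universe optional gene universe for the returned collection.
#' @return a [PathwayCollection-class].
#' @export
readGMT <- function(path, universe = NULL) {
    if (!file.exists(path)) .configError("missing file: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    nf <- lengths(strsplit(lines, "\t", fixed = TRUE))
    if (any(nf < 3))
        .formatError(path, ": GMT line ", which(nf < 3)[1],
                     " has fewer than 3 fields")
    sets <- fgsea::gmtPathways(path)
    dup <- vapply(sets, anyDuplicated, integer(1)) > 0
    if (any(dup))
        warning("duplicate genes removed in pathway(s): ",
                paste(names(sets)[dup], collapse = ", "))
    desc <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`, character(1), 2)
    PathwayCollection(lapply(sets, unique), description = desc,
                      universe = universe)
}

#' @rdname readGMT
#' @param pathways a [PathwayCollection-class] to write.
#' @export
writeGMT <- function(pathways, path) {
    sets <- pathwaySets(pathways)
    lines <- vapply(seq_along(sets), function(i) {
        paste(c(names(sets)[i], pathways@description[i], sets[[i]]),
              collapse = "\t")
    }, character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Assemble and validate a pipeline run configuration
#'
#' Collects input paths (or simulation specs), analysis thresholds and the
#' global seed; invalid settings raise a configuration error before any
#' computation starts. When `countsPath` is `NULL` the pipeline simulates
#' its inputs from `design`/`effects`.
#'
#' @param outDir output directory (created if absent).
#' @param seed global integer seed.
#' @param countsPath,samplesPath,bedPath,clusterPath,targetsPath,gmtPath
#'   optional input files; all-or-none for counts/samples.
#' @param design,effects simulation specs used when no counts are given.
#' @param alpha FDR threshold (default 0.05).
#' @param minCPM,minSamples expression-filter settings.
#' @param priorCount log2 CPM prior count (default 2).
#' @param ubiquitousThreshold log2 CPM cut-off (default 12).
#' @param k number of profile clusters (default 3).
#' @param clusterId genomic cluster to summarize (default `"C14MC"`).
#' @param nPerm enrichment permutations (default 10000).
#' @param skipEnrich disable the enrichment stage.
#' @return validated config list of class `"RunConfig"`.
#' @export
runConfig <- function(outDir, seed = 1L, countsPath = NULL,
                      samplesPath = NULL, bedPath = NULL, clusterPath = NULL,
                      targetsPath = NULL, gmtPath = NULL,
                      design = DesignSpec(), effects = EffectSpec(),
                      alpha = 0.05, minCPM = 1, minSamples = NULL,
                      priorCount = 2, ubiquitousThreshold = 12, k = 3L,
                      clusterId = "C14MC", nPerm = 10000L,
                      skipEnrich = FALSE) {
    if (alpha <= 0 || alpha >= 1) .configError("alpha must lie in (0, 1)")
    if (nPerm < 1) .configError("nPerm must be >= 1")
    if (xor(is.null(countsPath), is.null(samplesPath)))
        .configError("countsPath and samplesPath must be given together")
    for (p in c(countsPath, samplesPath, bedPath, clusterPath, targetsPath,
                gmtPath))
        if (!is.null(p) && !file.exists(p))
            .configError("input path does not exist: ", p)
    if (!skipEnrich && !is.null(countsPath) &&
        (is.null(targetsPath) || is.null(gmtPath)))
        .configError("enrichment enabled but targetsPath/gmtPath missing ",
                     "(use skipEnrich = TRUE or supply them)")
    structure(list(outDir = outDir, seed = as.integer(seed),
                   countsPath = countsPath, samplesPath = samplesPath,
                   bedPath = bedPath, clusterPath = clusterPath,
                   targetsPath = targetsPath, gmtPath = gmtPath,
                   design = design, effects = effects, alpha = alpha,
                   minCPM = minCPM, minSamples = minSamples,
                   priorCount = priorCount,
                   ubiquitousThreshold = ubiquitousThreshold,
                   k = as.integer(k), clusterId = clusterId,
                   nPerm = as.integer(nPerm), skipEnrich = skipEnrich),
              class = "RunConfig")
}

#' Run the full analysis pipeline
#'
#' Chains simulate (or load) -> filter -> TMM/log2 CPM -> temporal DE and
#' dynamics -> genotype contrasts and cluster summary -> target-pathway
#' enrichment, writing every result table as TSV plus a machine-readable
#' JSON run manifest (inputs, parameters, seed, package version, per-stage
#' dimensions) into `config$outDir`. The run is deterministic given the
#' config and seed.
#'
#' @param config a `RunConfig` from [runConfig()].
#' @return invisibly, a list with the in-memory results (`experiment`,
#'   `dynamics`, `genotype`, `clusterSummary`, `enrichment`, `manifest`).
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "RunConfig"))
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(config$outDir, f)
    ## outDir and absolute input paths are machine-specific and excluded so
    ## equal-seed runs produce byte-identical manifests
    manifest <- list(parameters = config[setdiff(names(config),
                                                 c("design", "effects",
                                                   "outDir"))],
                     package_version =
                         as.character(utils::packageVersion("EVmiRDyn")),
                     stages = list())

    ## stage 1: inputs
    if (is.null(config$countsPath)) {
        sim <- simulateCounts(config$design, config$effects,
                              seed = config$seed)
        exper <- sim$experiment
        annotation <- simulateAnnotation(sim$truth$labels,
                                         clusterId = config$clusterId,
                                         seed = config$seed)
        targets <- simulateTargetMap(sim$truth$labels, seed = config$seed)
        pathways <- simulatePathways(seed = config$seed,
                                     fixedSets = list(
                                         planted = .geneIds(2000L)[1:100]))
        writeCounts(exper, out("counts.tsv"), out("samples.tsv"))
        writeAnnotation(annotation, out("annotation.bed"),
                        out("clusters.tsv"))
        writeTargets(targets, out("targets.tsv"))
        writeGMT(pathways, out("pathways.gmt"))
        .writeTSV(sim$truth$labels, out("truth_labels.tsv"))
    } else {
        exper <- readCounts(config$countsPath, config$samplesPath)
        annotation <- if (!is.null(config$bedPath))
            readAnnotation(config$bedPath, config$clusterPath) else NULL
        targets <- if (!is.null(config$targetsPath))
            readTargets(config$targetsPath) else NULL
        pathways <- if (!is.null(config$gmtPath))
            readGMT(config$gmtPath) else NULL
    }
    manifest$stages$input <- dim(exper)

    ## stage 2: preprocessing
    exper <- filterLowExpression(exper, minCPM = config$minCPM,
                                 minSamples = config$minSamples)
    exper <- tmmNormalize(exper, priorCount = config$priorCount)
    .writeTSV(data.frame(sample_id = colnames(exper),
                         tmm_factor = unname(normFactors(exper)),
                         library_size = unname(librarySizes(exper))),
              out("tmm_factors.tsv"))
    .writeMatrixTSV(round(logCPM(exper), 6), out("logcpm.tsv"))
    manifest$stages$preprocessing <- dim(exper)

    ## stage 3: temporal dynamics (IC)
    dyn <- analyzeDynamics(exper, alpha = config$alpha, k = config$k,
                           ubiquitousThreshold = config$ubiquitousThreshold)
    for (rg in names(dyn$deTables))
        for (ct in names(dyn$deTables[[rg]]))
            .writeTSV(dyn$deTables[[rg]][[ct]],
                      out(paste0("de_temporal_", rg, "_", ct, ".tsv")))
    .writeTSV(dyn$dynamic, out("dynamic_set.tsv"))
    if (!is.null(dyn$clustering)) {
        .writeTSV(data.frame(mirna_id = names(dyn$clustering$labels),
                             cluster = unname(dyn$clustering$labels)),
                  out("cluster_labels.tsv"))
        .writeMatrixTSV(round(dyn$profiles, 6), out("profiles.tsv"))
    }
    .writeTSV(data.frame(mirna_id = dyn$ubiquitous), out("ubiquitous.tsv"))
    manifest$stages$dynamics <- c(dynamic = nrow(dyn$dynamic),
                                  ubiquitous = length(dyn$ubiquitous))

    ## stage 4: genotype contrasts + cluster summary
    gde <- genotypeDE(exper)
    for (nm in names(gde))
        .writeTSV(gde[[nm]], out(paste0("de_genotype_", nm, ".tsv")))
    dun <- differentialUnion(gde, alpha = config$alpha)
    .writeMatrixTSV(round(dun$log2fc, 6), out("log2fc_matrix.tsv"))
    clSum <- NULL
    if (!is.null(annotation) &&
        config$clusterId %in% S4Vectors::mcols(annotation)$cluster_id) {
        clSum <- clusterSummary(exper, gde, annotation, config$clusterId,
                                alpha = config$alpha)
        .writeTSV(data.frame(cluster_id = clSum$cluster_id,
                             n_members = clSum$n_members,
                             n_tested = clSum$n_tested,
                             n_significant = clSum$n_significant,
                             fraction_significant =
                                 clSum$fraction_significant),
                  out("cluster_summary.tsv"))
        .writeMatrixTSV(round(clSum$condition_means, 6),
                        out("cluster_condition_means.tsv"))
    }
    manifest$stages$genotype <- c(comparisons = length(gde),
                                  union = length(dun$mirna_ids))

    ## stage 5: enrichment on the three miRNA sets of interest
    enr <- NULL
    if (!config$skipEnrich && !is.null(targets) && !is.null(pathways)) {
        pool <- union(mirnaPool(targets), rownames(exper))
        targets <- MiRNATargets(targetSets(targets), pool = pool)
        sets <- list(dynamic = dyn$dynamic$mirna_id,
                     ubiquitous = dyn$ubiquitous,
                     genotype = dun$mirna_ids)
        enr <- list()
        i <- 0L
        for (nm in names(sets)) {
            i <- i + 1L
            tab <- permutationPvalues(sets[[nm]], targets, pathways,
                                      nPerm = config$nPerm,
                                      seed = deriveSeed(config$seed, 40L + i))
            enr[[nm]] <- tab
            .writeTSV(tab, out(paste0("enrichment_", nm, ".tsv")))
        }
        manifest$stages$enrichment <- lengths(sets)
    }

    manifest$stages <- lapply(manifest$stages, as.list)
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, null = "null", digits = NA)
    invisible(list(experiment = exper, dynamics = dyn, genotype = gde,
                   union = dun, clusterSummary = clSum, enrichment = enr,
                   manifest = manifest))
}
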