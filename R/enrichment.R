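## Over-representation analysis of miRNA target-gene unions against pathway
## gene sets, with a size-matched miRNA-set permutation null.

#' Union of target genes of a miRNA set
#'
#' @param mirnaSet character vector of miRNA ids.
#' @param targets a [MiRNATargets-class].
#' @return character vector: the union of the members' target sets (empty
#'   when none targets anything). miRNAs in the pool but absent from the
#'   map contribute nothing; ids outside the pool are an error.
#' @export
targetUnion <- function(mirnaSet, targets) {
    stopifnot(is(targets, "MiRNATargets"))
    unknown <- setdiff(mirnaSet, mirnaPool(targets))
    if (length(unknown))
        stop("miRNA id(s) not in the sampling pool: ",
             paste(unknown, collapse = ", "))
    m <- targetSets(targets)
    unique(unlist(m[intersect(mirnaSet, names(m))], use.names = FALSE))
}

#' Upper-tail hypergeometric over-representation p-value
#'
#' `P(X >= k)` for the overlap `k` of a query gene set with a pathway of
#' size `K` inside a universe of size `N`, drawing `n = |query|` genes.
#' Query or pathway genes outside the universe are dropped (their count is
#' reported via attribute `dropped`).
#'
#' @param query character vector of query genes.
#' @param pathway character vector of pathway genes.
#' @param universe character vector, the eligible gene universe.
#' @return the p-value, with attributes `k`, `n`, `K`, `N`, `dropped`.
#' @export
ora <- function(query, pathway, universe) {
    universe <- unique(universe)
    N <- length(universe)
    if (N == 0) stop("empty gene universe")
    q0 <- unique(query); p0 <- unique(pathway)
    query <- intersect(q0, universe)
    pathway <- intersect(p0, universe)
    dropped <- (length(q0) - length(query)) + (length(p0) - length(pathway))
    k <- length(intersect(query, pathway))
    n <- length(query); K <- length(pathway)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    structure(p, k = k, n = n, K = K, N = N, dropped = dropped)
}

#' Over-representation analysis across a pathway collection
#'
#' Applies [ora()] to every pathway and BH-adjusts across the collection.
#'
#' @param query character vector of query genes.
#' @param pathways a [PathwayCollection-class].
#' @param universe optional universe; defaults to the collection's.
#' @return `EnrichmentTable` data.frame with columns `pathway`, `overlap`,
#'   `query_size`, `pathway_size`, `universe_size`, `p_value`, `q_value`.
#' @export
oraCollection <- function(query, pathways, universe = NULL) {
    stopifnot(is(pathways, "PathwayCollection"))
    if (is.null(universe)) universe <- geneUniverse(pathways)
    sets <- pathwaySets(pathways)
    rows <- lapply(names(sets), function(nm) {
        p <- ora(query, sets[[nm]], universe)
        data.frame(pathway = nm, overlap = attr(p, "k"),
                   query_size = attr(p, "n"), pathway_size = attr(p, "K"),
                   universe_size = attr(p, "N"), p_value = as.numeric(p))
    })
    out <- do.call(rbind, rows)
    out$q_value <- bhAdjust(out$p_value)
    out
}

#' Permutation p-values for pathway enrichment of a miRNA set
#'
#' Calibrates the hypergeometric enrichment of the observed miRNA set's
#' target union against the null distribution generated by size-matched
#' random miRNA sets: each of `nPerm` permutations draws, without
#' replacement, a set of the same size from the sampling pool, forms its
#' target union, and recomputes every pathway's hypergeometric p on the
#' same permuted set (preserving cross-pathway correlation). The
#' permutation p-value per pathway is `(b + 1) / (nPerm + 1)`, where `b`
#' counts permuted p-values less than or equal to the observed one (ties
#' count); `paperParity = TRUE` reports `b / nPerm` instead.
#'
#' @param mirnaSet observed miRNA set (character).
#' @param targets a [MiRNATargets-class]; its pool is the sampling frame.
#' @param pathways a [PathwayCollection-class].
#' @param universe optional gene universe (default: the collection's).
#' @param nPerm number of permutations (default 10000).
#' @param seed integer seed for the permutation stream.
#' @param paperParity report `b / nPerm` instead of `(b+1)/(nPerm+1)`.
#' @return `EnrichmentTable` data.frame: the [oraCollection()] columns plus
#'   `perm_b`, `n_perm`, `perm_p`.
#' @export
permutationPvalues <- function(mirnaSet, targets, pathways, universe = NULL,
                               nPerm = 10000L, seed = 1L,
                               paperParity = FALSE) {
    stopifnot(is(targets, "MiRNATargets"), is(pathways, "PathwayCollection"))
    if (nPerm < 1) stop("nPerm must be >= 1")
    if (is.null(universe)) universe <- geneUniverse(pathways)
    universe <- unique(universe)
    N <- length(universe)
    if (N == 0) stop("empty gene universe")
    pool <- mirnaPool(targets)
    if (length(mirnaSet) > length(pool))
        stop("observed set is larger than the sampling pool")
    obs <- oraCollection(targetUnion(mirnaSet, targets), pathways, universe)
    if (length(mirnaSet) == 0) {
        warning("observed miRNA set is empty; permutation p set to 1")
        obs$perm_b <- nPerm; obs$n_perm <- nPerm; obs$perm_p <- 1
        return(obs)
    }
    ## incidence of universe genes in each pathway, for fast per-perm overlap
    sets <- pathwaySets(pathways)
    inc <- vapply(sets, function(g) universe %in% g,
                  logical(N))                     # N x P
    K <- colSums(inc)
    m <- length(mirnaSet)
    map <- targetSets(targets)
    ## target sets pre-restricted to the universe, as universe indices
    idx <- lapply(map, function(g) which(universe %in% g))
    b <- numeric(ncol(inc))
    set.seed(seed)
    for (r in seq_len(nPerm)) {
        draw <- sample(pool, m)
        u <- unique(unlist(idx[intersect(draw, names(idx))],
                           use.names = FALSE))
        n <- length(u)
        k <- if (n) colSums(inc[u, , drop = FALSE]) else numeric(ncol(inc))
        pp <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
        b <- b + (pp <= obs$p_value + 1e-12)
    }
    obs$perm_b <- b
    obs$n_perm <- nPerm
    obs$perm_p <- if (paperParity) b / nPerm else (b + 1) / (nPerm + 1)
    obs
}
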