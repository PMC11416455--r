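test_that("default design yields 14 condition cells and 42 samples", {
    cells <- conditionCells()
    expect_equal(nrow(cells), 14)
    expect_equal(sum(cells$region == "iPSC"), 2)     # one D0 cell/genotype
    expect_true(all(cells$timepoint[cells$region == "iPSC"] == "D0"))
    expect_true(all(cells$timepoint[cells$region != "iPSC"] != "D0"))
    sim <- simulateCounts(DesignSpec(nMirnas = 30, meanLibSize = 2e4),
                          EffectSpec(0, 0, 0, 0), seed = 1)
    expect_equal(ncol(sim$experiment), 42)
    expect_equal(nrow(sim$truth$labels), 30)
    expect_true(validObject(sim$experiment))
})

test_that("identical seed and specs reproduce bit-identical output", {
    d <- DesignSpec(nMirnas = 40, meanLibSize = 3e4)
    e <- EffectSpec(nIncreasing = 3, nDecreasing = 3, nGenotypeCluster = 4,
                    nUbiquitous = 2)
    s1 <- simulateCounts(d, e, seed = 123)
    s2 <- simulateCounts(d, e, seed = 123)
    expect_identical(counts(s1$experiment), counts(s2$experiment))
    expect_identical(s1$truth, s2$truth)
    s3 <- simulateCounts(d, e, seed = 124)
    expect_false(identical(counts(s1$experiment), counts(s3$experiment)))
})

test_that("degenerate settings give iid Poisson columns", {
    ## dispersion 0, CV 0, all effects 0: every column Poisson with the
    ## same mean vector
    d <- DesignSpec(nMirnas = 200, meanLibSize = 2e5, libSizeCV = 0,
                    nbDispersion = 0)
    sim <- simulateCounts(d, EffectSpec(0, 0, 0, 0,
                                        compositionBiasFraction = 0),
                          seed = 9)
    cnt <- counts(sim$experiment)
    mu <- 2^sim$truth$trueLog2CPM[, 1] / 1e6 * 2e5
    ## same true mean vector in every condition
    expect_equal(max(apply(sim$truth$trueLog2CPM, 1, function(r)
        diff(range(r)))), 0, tolerance = 1e-12)
    ## empirical row means near mu, variance ~ mean (Poisson)
    big <- mu > 20
    expect_lt(max(abs(rowMeans(cnt)[big] / mu[big] - 1)), 0.25)
    vm <- apply(cnt[big, ], 1, var) / rowMeans(cnt[big, ])
    expect_equal(mean(vm), 1, tolerance = 0.1)
})

test_that("per-condition count means converge to library x abundance", {
    ## many replicates of a single design: relative error < 5%
    d <- DesignSpec(replicates = 1000, nMirnas = 25, meanLibSize = 2e4,
                    libSizeCV = 0, nbDispersion = 0.1)
    sim <- simulateCounts(d, EffectSpec(2, 2, 3, 2), seed = 33)
    cnt <- counts(sim$experiment)
    cd <- colData(sim$experiment)
    cond <- paste(cd$genotype, cd$region, cd$timepoint, sep = "_")
    for (cc in unique(cond)[c(1, 5, 9)]) {
        mu <- 2^sim$truth$trueLog2CPM[, cc] / 1e6 * 2e4
        est <- rowMeans(cnt[, cond == cc])
        keep <- mu > 5
        expect_lt(max(abs(est[keep] / mu[keep] - 1)), 0.05)
    }
    ## overdispersion: variance exceeds the mean when dispersion > 0
    vm <- apply(cnt[, cond == unique(cond)[1]], 1, var) /
        rowMeans(cnt[, cond == unique(cond)[1]])
    expect_gt(median(vm), 1.5)
})

test_that("planted monotone classes are monotone in true condition means", {
    sim <- simulateCounts(DesignSpec(nMirnas = 50),
                          EffectSpec(nIncreasing = 5, nDecreasing = 5,
                                     nGenotypeCluster = 0, nUbiquitous = 0),
                          seed = 3)
    lab <- sim$truth$labels
    tl <- sim$truth$trueLog2CPM
    cells <- sim$truth$conditions
    icDorsal <- cells$condition[cells$genotype == "IC" &
                                cells$region %in% c("iPSC", "dorsal")]
    ord <- icDorsal[order(match(sub(".*_", "", icDorsal),
                                c("D0", "D13", "D40", "D75")))]
    for (i in which(lab$class == "increasing"))
        expect_true(all(diff(tl[i, ord]) > 0))
    for (i in which(lab$class == "decreasing"))
        expect_true(all(diff(tl[i, ord]) < 0))
    ## every miRNA has exactly one class
    expect_true(all(lab$class %in% c("null", "increasing", "decreasing",
                                     "genotype_elevated", "ubiquitous")))
})

test_that("invalid specs are rejected", {
    expect_error(simulateCounts(DesignSpec(nMirnas = 10),
                                EffectSpec(nIncreasing = 20), seed = 1),
                 "exceed")
    expect_error(DesignSpec(replicates = 0), "replicates")
    expect_error(EffectSpec(compositionBiasFraction = 2), "0, 1")
})

test_that("simulated annotation places the cluster as specified", {
    lab <- data.frame(mirna_id = paste0("m", 1:20),
                      class = rep(c("genotype_elevated", "null"),
                                  c(15, 5)),
                      composition_biased = FALSE)
    locus <- GRanges("chr14", IRanges::IRanges(1001, 16000))  # 15 kb
    ann <- simulateAnnotation(lab, clusterLocus = locus, seed = 2,
                              featureWidth = 80)
    cl <- ann[!is.na(mcols(ann)$cluster_id)]
    expect_length(cl, 15)
    ## disjoint intervals inside the locus, sorted by miRNA index
    expect_true(all(GenomicRanges::end(cl) <= GenomicRanges::end(locus)))
    expect_true(all(GenomicRanges::start(cl) >=
                    GenomicRanges::start(locus)))
    expect_equal(order(GenomicRanges::start(cl)), seq_len(15))
    red <- GenomicRanges::reduce(cl)
    expect_length(red, 15)                     # no overlaps merged away
    ## no cluster labels at all when the class is absent
    lab2 <- lab; lab2$class <- "null"
    ann2 <- simulateAnnotation(lab2, clusterLocus = locus, seed = 2)
    expect_true(all(is.na(mcols(ann2)$cluster_id)))
    ## locus too small is an error
    tiny <- GRanges("chr14", IRanges::IRanges(1, 800))
    expect_error(simulateAnnotation(lab, clusterLocus = tiny, seed = 2),
                 "too small")
    ## reproducibility
    expect_identical(simulateAnnotation(lab, clusterLocus = locus,
                                        seed = 5),
                     simulateAnnotation(lab, clusterLocus = locus,
                                        seed = 5))
})

test_that("simulated target map honours class enrichment and edge cases", {
    lab <- data.frame(mirna_id = paste0("m", 1:30),
                      class = rep(c("genotype_elevated", "null"),
                                  c(10, 20)),
                      composition_biased = FALSE)
    ## constant 0 targets: every set empty
    tm0 <- simulateTargetMap(lab, nGenes = 100, meanTargets = 0, seed = 1)
    expect_true(all(lengths(targetSets(tm0)) == 0))
    expect_setequal(mirnaPool(tm0), lab$mirna_id)
    ## full enrichment: union of the class's targets within the block
    tm1 <- simulateTargetMap(lab, nGenes = 500, meanTargets = 10,
                             enrichedPathwayFraction = 1, seed = 4,
                             nEnrichedGenes = 50)
    block <- sprintf("G%05d", 1:50)
    u <- targetUnion(lab$mirna_id[lab$class == "genotype_elevated"], tm1)
    expect_true(all(u %in% block))
    ## reproducibility
    expect_identical(targetSets(simulateTargetMap(lab, seed = 8)),
                     targetSets(simulateTargetMap(lab, seed = 8)))
})

test_that("simulated pathways cover the stated degenerate cases", {
    pc <- simulatePathways(nPathways = 0, nGenes = 40, seed = 1,
                           fixedSets = list(all = sprintf("G%05d", 1:40)))
    expect_equal(pathwaySets(pc)$all, sprintf("G%05d", 1:40))
    expect_length(geneUniverse(pc), 40)
    pc2 <- simulatePathways(nPathways = 12, meanGenesPerPathway = 8,
                            nGenes = 200, seed = 6)
    expect_identical(pathwaySets(pc2),
                     pathwaySets(simulatePathways(nPathways = 12,
                                                  meanGenesPerPathway = 8,
                                                  nGenes = 200, seed = 6)))
    expect_true(all(unlist(pathwaySets(pc2)) %in% geneUniverse(pc2)))
})

test_that("container validity enforces the design vocabulary", {
    cnt <- matrix(1:4, 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
    ok <- data.frame(genotype = "IC", region = "iPSC", timepoint = "D0",
                     replicate = 1:2, row.names = c("s1", "s2"))
    expect_s4_class(MiRNAExperiment(cnt, ok), "MiRNAExperiment")
    bad <- ok; bad$timepoint <- "D13"           # D13 in iPSC is invalid
    expect_error(MiRNAExperiment(cnt, bad), "D0")
    bad2 <- ok; bad2$genotype <- "WT"
    expect_error(MiRNAExperiment(cnt, bad2), "IC or RTT")
    neg <- cnt; neg[1] <- -1
    expect_error(MiRNAExperiment(neg, ok), "non-negative")
})
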