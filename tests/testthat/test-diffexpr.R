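test_that("NB GLM recovers closed forms in degenerate designs", {
    ## one-group Poisson: coefficient is log(sum y / sum lib)
    y <- c(10, 20, 15, 12)
    lib <- c(1e4, 2e4, 1.5e4, 1.2e4)
    f <- fitNBGLM(y, matrix(1, 4, 1), log(lib), dispersion = 0)
    expect_equal(unname(f$coefficients), log(sum(y) / sum(lib)),
                 tolerance = 1e-7)
    expect_true(f$converged)
    ## saturated design: one coefficient per sample, zero residual deviance
    fs <- fitNBGLM(y, diag(4), log(lib), dispersion = 0.1)
    expect_equal(fs$deviance, 0, tolerance = 1e-6)
    expect_equal(fs$fitted, y, tolerance = 1e-5)
})

test_that("NB GLM deviance matches a grid-search likelihood oracle", {
    ## 3 vs 3 toy with equal offsets; group-mean MLEs found by independent
    ## 1-D likelihood maximization per group
    y <- c(12, 30, 21, 60, 45, 70)
    X <- cbind(g1 = c(1, 1, 1, 0, 0, 0), g2 = c(0, 0, 0, 1, 1, 1))
    off <- rep(log(1e4), 6)
    phi <- 0.15
    nbll <- function(y, mu) sum(dnbinom(y, size = 1 / phi, mu = mu,
                                        log = TRUE))
    m1 <- optimize(function(m) nbll(y[1:3], rep(m, 3)),
                   c(1, 200), maximum = TRUE)$maximum
    m2 <- optimize(function(m) nbll(y[4:6], rep(m, 3)),
                   c(1, 200), maximum = TRUE)$maximum
    devOracle <- 2 * (nbll(y, y) - (nbll(y[1:3], rep(m1, 3)) +
                                    nbll(y[4:6], rep(m2, 3))))
    f <- fitNBGLM(y, X, off, phi)
    expect_equal(f$deviance, devOracle, tolerance = 1e-5)
    expect_equal(unname(exp(f$coefficients + log(1e4))), c(m1, m2),
                 tolerance = 1e-4)
})

test_that("trended dispersion is near zero for Poisson counts", {
    sim <- simulateCounts(DesignSpec(nMirnas = 2000, nbDispersion = 0),
                          EffectSpec(0, 0, 0, 0), seed = 3)
    x <- sim$experiment
    sel <- colData(x)$region == "iPSC"          # 3 vs 3
    sub <- x[, sel]
    X <- model.matrix(~ 0 + factor(colData(sub)$genotype))
    d <- estimateDispersions(sub, X, log(colSums(counts(sub))))
    expect_gte(mean(d@trended <= 0.01), 0.95)
})

test_that("trended dispersion recovers a planted NB dispersion at n = 12", {
    sim <- simulateCounts(DesignSpec(nMirnas = 500, nbDispersion = 0.1),
                          EffectSpec(0, 0, 0, 0), seed = 8)
    x <- sim$experiment
    cd <- colData(x)
    sel <- cd$genotype == "IC" & cd$region %in% c("iPSC", "dorsal")
    sub <- x[, sel]                              # 4 timepoints x 3 = 12
    tp <- factor(colData(sub)$timepoint)
    X <- model.matrix(~ 0 + tp)
    d <- estimateDispersions(sub, X, log(colSums(counts(sub))))
    expect_gte(median(d@trended), 0.07)
    expect_lte(median(d@trended), 0.13)
})

test_that("dispersion estimation demands at least one residual df", {
    y <- matrix(rpois(40, 50), 10, 4)
    expect_error(estimateDispersions(y, diag(4), log(colSums(y))),
                 "common quasi-dispersion")
})

test_that("quasi-dispersion shrinkage matches its scaled-F moment model", {
    ## identical quasi-dispersions need no shrinkage: infinite prior df
    sq <- squeezeQuasiDispersions(rep(1.3, 20), df = 8)
    expect_identical(sq$priorDF, Inf)
    expect_equal(sq$squeezed, rep(1.3, 20), tolerance = 1e-9)
    ## squeezed values lie between raw and prior values
    set.seed(4)
    s2 <- exp(rnorm(300, 0, 1))
    sq2 <- squeezeQuasiDispersions(s2, df = 8)
    expect_true(all((sq2$squeezed - s2) * (sq2$s0 - s2) >= -1e-12))
    ## cross-check against the reference EB implementation
    skip_if_not_installed("limma")
    ref <- limma::squeezeVar(s2, df = 8)
    expect_equal(sq2$priorDF, ref$df.prior, tolerance = 1e-6)
    expect_equal(sq2$squeezed, ref$var.post, tolerance = 1e-6)
})

test_that("QL F-test returns F = 0, p = 1 for identical groups", {
    y <- matrix(rep(c(50, 60, 70, 50, 60, 70), each = 8), 8, 6, byrow = FALSE)
    rownames(y) <- paste0("m", 1:8)
    X <- cbind(a = rep(1:0, each = 3), b = rep(0:1, each = 3))
    off <- rep(log(1e4), 6)
    d <- estimateDispersions(y, X, off)
    tab <- qlFTest(y, X, c(1, -1), d, off)
    expect_equal(tab$f_stat, rep(0, 8), tolerance = 1e-6)
    expect_equal(tab$p_value, rep(1, 8), tolerance = 1e-6)
    expect_equal(tab$log2fc, rep(0, 8), tolerance = 1e-4)
    ## a zero contrast is a precondition violation
    expect_error(qlFTest(y, X, c(0, 0), d, off), "non-zero")
})

test_that("QL p-values agree with classical ANOVA in the Poisson limit", {
    ## large counts, dispersion ~ 0: the F statistic ranking should agree
    ## with one-way ANOVA on log counts within Monte-Carlo tolerance
    set.seed(10)
    G <- 300
    y <- matrix(rpois(G * 6, 5000), G, 6,
                dimnames = list(paste0("m", 1:G), NULL))
    X <- cbind(a = rep(1:0, each = 3), b = rep(0:1, each = 3))
    off <- rep(log(3e4), 6)
    d <- estimateDispersions(y, X, off)
    tab <- qlFTest(y, X, c(1, -1), d, off)
    grp <- factor(rep(1:2, each = 3))
    pAov <- apply(y, 1, function(r)
        summary(aov(log(r) ~ grp))[[1]][["Pr(>F)"]][1])
    expect_gt(cor(tab$p_value, pAov, method = "spearman"), 0.9)
    expect_lt(abs(mean(tab$p_value < 0.05) - 0.05), 0.03)
})

test_that("planted two-fold effects: power and parity with the reference", {
    ## dispersion 0.1, n = 3 per group, depth 1e6, baseline CPM >= 50
    set.seed(12)
    G <- 400; nDE <- 40
    baseCPM <- exp(runif(G, log(50), log(2000)))
    mu <- outer(baseCPM, rep(1, 6))
    mu[seq_len(nDE), 4:6] <- mu[seq_len(nDE), 4:6] * 2
    y <- matrix(rnbinom(G * 6, mu = mu, size = 10), G, 6,
                dimnames = list(paste0("m", 1:G), NULL))
    X <- cbind(a = rep(1:0, each = 3), b = rep(0:1, each = 3))
    off <- rep(log(1e6), 6)
    d <- estimateDispersions(y, X, off)
    tab <- qlFTest(y, X, c(-1, 1), d, off)
    ## most planted effects rank above the null background
    expect_gte(mean(tab$p_value[seq_len(nDE)] < 0.05), 0.5)
    ## fold-change estimates centred on the planted log2 FC of 1
    expect_equal(mean(tab$log2fc[seq_len(nDE)]), 1, tolerance = 0.15)
    ## parity: sensitivity within a few hits of the reference QL pipeline
    skip_if_not_installed("edgeR")
    dg <- edgeR::DGEList(y, lib.size = rep(1e6, 6))
    Xe <- cbind(1, grp = rep(0:1, each = 3))
    dg <- edgeR::estimateDisp(dg, Xe)
    fit <- edgeR::glmQLFit(dg, Xe)
    te <- edgeR::topTags(edgeR::glmQLFTest(fit, coef = 2), n = Inf,
                         sort.by = "none")$table
    sensMine <- mean(tab$q_value[seq_len(nDE)] < 0.05)
    sensRef <- mean(te$FDR[seq_len(nDE)] < 0.05)
    expect_lt(abs(sensMine - sensRef), 0.1)
})

test_that("BH adjustment follows the step-up rule and handles NA", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
    expect_equal(bhAdjust(0.4), 0.4)
    expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
    q <- bhAdjust(c(0.01, NA, 0.04))
    expect_true(is.na(q[2]))
    expect_equal(q[c(1, 3)], p.adjust(c(0.01, 0.04), "BH"))
    expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")
    ## q is monotone in p and q >= p
    set.seed(6)
    p <- runif(50)
    q <- bhAdjust(p)
    expect_true(all(q >= p - 1e-12))
    expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("temporalDE and genotypeDE wire subsets and contrasts correctly", {
    sim <- simulateCounts(DesignSpec(nMirnas = 80, meanLibSize = 1e5),
                          EffectSpec(0, 0, 0, 0), seed = 21)
    x <- tmmNormalize(sim$experiment)
    de <- temporalDE(x, "dorsal")
    expect_named(de, names(temporalContrasts()))
    expect_equal(nrow(de[[1]]), nrow(x))
    gde <- genotypeDE(x)
    expect_length(gde, 7)
    expect_true(all(c("iPSC_D0", "dorsal_D75", "ventral_D13") %in%
                    names(gde)))
    ## swapping genotype labels flips every log2 fold-change sign
    x2 <- x
    cd <- colData(x2)
    cd$genotype <- ifelse(cd$genotype == "IC", "RTT", "IC")
    colData(x2) <- cd
    g1 <- gde[["iPSC_D0"]]
    g2 <- genotypeDE(x2)[["iPSC_D0"]]
    expect_equal(g2$log2fc, -g1$log2fc, tolerance = 1e-5)
})
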