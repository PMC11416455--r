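## Negative-binomial generalized linear models with a log link, trended
## Cox-Reid dispersion estimation, and the quasi-likelihood F-test with
## empirical-Bayes moderated quasi-dispersions.

.nbDeviance <- function(y, mu, phi) {
    mu <- pmax(mu, 1e-300)
    t1 <- ifelse(y > 0, y * log(y / mu), 0)
    if (phi <= 0) {
        2 * sum(t1 - (y - mu))
    } else {
        2 * sum(t1 - (y + 1 / phi) * log((1 + phi * y) / (1 + phi * mu)))
    }
}

.nbLogLik <- function(y, mu, phi) {
    if (phi <= 0) sum(stats::dpois(y, mu, log = TRUE))
    else sum(stats::dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
}

#' Fit a log-link negative-binomial GLM to one count row
#'
#' Iteratively reweighted least squares at a fixed dispersion, with the IRLS
#' weights `mu / (1 + phi * mu)` of the NB log link. Convergence is declared
#' when the deviance changes by less than `tol` (relative), within `maxit`
#' iterations.
#'
#' @param y counts for one miRNA (length = samples).
#' @param design design matrix (samples x coefficients), full column rank.
#' @param offsets log effective library sizes.
#' @param dispersion NB dispersion (0 = Poisson).
#' @param start optional starting coefficients.
#' @param tol,maxit convergence tolerance (1e-8) and iteration cap (100).
#' @return list with `coefficients`, `fitted` (means), `deviance`,
#'   `converged`, and `cr` (half log-determinant of the weighted information,
#'   the Cox-Reid adjustment term).
#' @export
fitNBGLM <- function(y, design, offsets, dispersion, start = NULL,
                     tol = 1e-8, maxit = 100L) {
    X <- as.matrix(design)
    n <- length(y)
    stopifnot(nrow(X) == n, length(offsets) == n)
    phi <- dispersion
    if (is.null(start)) {
        mu <- pmax(y, mean(y) / 8, 1e-4)
        eta <- log(mu)
        beta <- qr.coef(qr(X), eta - offsets)
        beta[is.na(beta)] <- 0
    } else beta <- start
    dev <- Inf; converged <- FALSE
    for (it in seq_len(maxit)) {
        eta <- drop(X %*% beta) + offsets
        eta <- pmin(eta, 700)
        mu <- pmax(exp(eta), 1e-10)
        w <- mu / (1 + phi * mu)
        z <- (eta - offsets) + (y - mu) / mu
        xtw <- t(X * w)
        beta.new <- tryCatch(solve(xtw %*% X, xtw %*% z),
                             error = function(e) NULL)
        if (is.null(beta.new)) break
        beta <- drop(beta.new)
        dev.new <- .nbDeviance(y, pmax(exp(pmin(drop(X %*% beta) + offsets,
                                                700)), 1e-10), phi)
        if (is.finite(dev.new) &&
            abs(dev.new - dev) < tol * (abs(dev.new) + 0.1)) {
            dev <- dev.new; converged <- TRUE; break
        }
        dev <- dev.new
    }
    eta <- pmin(drop(X %*% beta) + offsets, 700)
    mu <- pmax(exp(eta), 1e-10)
    w <- mu / (1 + phi * mu)
    info <- t(X * w) %*% X
    cr <- 0.5 * as.numeric(determinant(info, logarithm = TRUE)$modulus)
    list(coefficients = beta, fitted = mu,
         deviance = .nbDeviance(y, mu, phi), converged = converged, cr = cr)
}

## Fit every row of a count matrix at one dispersion (scalar or per-row).
.fitManyNB <- function(cnt, X, offsets, phi, start = NULL) {
    G <- nrow(cnt); p <- ncol(X)
    phi <- rep_len(phi, G)
    coefs <- matrix(NA_real_, G, p)
    dev <- cr <- numeric(G); conv <- logical(G)
    for (g in seq_len(G)) {
        f <- fitNBGLM(cnt[g, ], X, offsets, phi[g],
                      start = if (is.null(start)) NULL else start[g, ])
        coefs[g, ] <- f$coefficients
        dev[g] <- f$deviance; cr[g] <- f$cr; conv[g] <- f$converged
    }
    list(coefficients = coefs, deviance = dev, cr = cr, converged = conv)
}

.aveLogCPM <- function(cnt, offsets, priorCount = 2) {
    effLib <- exp(offsets)
    prior <- priorCount * effLib / mean(effLib)
    rowMeans(t(log2((t(cnt) + prior) / (effLib + 2 * prior) * 1e6)))
}

## Cox-Reid adjusted profile log-likelihood of one gene at one dispersion.
.aplOne <- function(y, X, offsets, phi, start = NULL) {
    f <- fitNBGLM(y, X, offsets, phi, start = start)
    .nbLogLik(y, f$fitted, phi) - f$cr
}

#' Estimate trended NB dispersions and moderated quasi-dispersions
#'
#' The negative-binomial layer: per-miRNA Cox-Reid adjusted profile
#' log-likelihoods are evaluated on a geometric dispersion grid, summed
#' within abundance bins (miRNAs grouped by average log2 CPM), maximized per
#' bin with quadratic interpolation on the log-dispersion scale, and the
#' binned estimates are smoothed against abundance (lowess) to give a
#' trended dispersion per miRNA. The quasi layer: each miRNA is refitted at
#' its trended dispersion; its quasi-dispersion is residual deviance over
#' residual df, and an empirical-Bayes step (moment matching of the log
#' quasi-dispersions to a scaled-F model) estimates a prior df and returns
#' squeezed values.
#'
#' @param x a [MiRNAExperiment-class] or count matrix.
#' @param design design matrix (samples x coefficients).
#' @param offsets log effective library sizes; taken from the object when
#'   normalized.
#' @param dispGrid dispersion grid (default 15 points, 1e-4 to 2).
#' @param nBins target number of abundance bins (minimum 10 when enough
#'   miRNAs are available).
#' @return a [DispersionEstimates-class] object.
#' @export
estimateDispersions <- function(x, design, offsets = NULL,
                                dispGrid = exp(seq(log(1e-4), log(2),
                                                   length.out = 15)),
                                nBins = 10L) {
    cnt <- if (is(x, "MiRNAExperiment")) counts(x) else as.matrix(x)
    if (is.null(offsets)) {
        offsets <- if (is(x, "MiRNAExperiment") &&
                       "norm.factor" %in% colnames(colData(x)))
            effectiveLibOffsets(x) else log(colSums(cnt))
    }
    X <- as.matrix(design)
    G <- nrow(cnt); n <- nrow(X); p <- ncol(X)
    if (qr(X)$rank < p) stop("design matrix is not of full column rank")
    residDF <- n - p
    if (residDF < 1)
        stop("residual df is zero; use a common quasi-dispersion ",
             "(saturated design cannot support per-miRNA quasi-dispersions)")
    abundance <- .aveLogCPM(cnt, offsets)

    ## APL on the grid, warm-started along the grid
    K <- length(dispGrid)
    apl <- matrix(NA_real_, G, K)
    start <- NULL
    for (k in seq_len(K)) {
        fit <- .fitManyNB(cnt, X, offsets, dispGrid[k], start = start)
        ll <- vapply(seq_len(G), function(g) {
            mu <- pmax(exp(pmin(drop(X %*% fit$coefficients[g, ]) + offsets,
                                700)), 1e-10)
            .nbLogLik(cnt[g, ], mu, dispGrid[k])
        }, numeric(1))
        apl[, k] <- ll - fit$cr
        start <- fit$coefficients
    }

    nBins <- max(1L, min(as.integer(nBins), floor(G / 10)))
    bin <- if (nBins > 1)
        cut(rank(abundance, ties.method = "first"), nBins, labels = FALSE)
    else rep(1L, G)
    logGrid <- log(dispGrid)
    binDisp <- binAbund <- numeric(nBins)
    for (b in seq_len(nBins)) {
        rows <- which(bin == b)
        tot <- colSums(apl[rows, , drop = FALSE])
        m <- which.max(tot)
        if (m > 1 && m < K) {
            ## quadratic interpolation around the grid maximum
            xs <- logGrid[(m - 1):(m + 1)]; ys <- tot[(m - 1):(m + 1)]
            den <- (ys[1] - 2 * ys[2] + ys[3])
            lphi <- if (den < 0)
                xs[2] - 0.5 * (xs[2] - xs[1]) * (ys[3] - ys[1]) / den
            else logGrid[m]
        } else lphi <- logGrid[m]
        binDisp[b] <- exp(lphi)
        binAbund[b] <- mean(abundance[rows])
    }
    trended <- if (nBins >= 4) {
        lo <- stats::lowess(binAbund, log(binDisp), f = 0.5)
        exp(stats::approx(lo$x, lo$y, xout = abundance, rule = 2)$y)
    } else rep(exp(mean(log(binDisp))), G)

    ## quasi-dispersions at the trended NB dispersion
    fit <- .fitManyNB(cnt, X, offsets, trended)
    s2 <- fit$deviance / residDF
    sq <- squeezeQuasiDispersions(s2, residDF)
    new("DispersionEstimates", trended = trended, aveLogCPM = abundance,
        quasi = s2, quasiSqueezed = sq$squeezed, priorDF = sq$priorDF,
        residDF = residDF)
}

## Newton inversion of the trigamma function (for the moment-matching step).
.trigammaInverse <- function(y) {
    if (y > 1e7) return(1 / sqrt(y))
    if (y < 1e-6) return(1 / y)
    x <- 0.5 + 1 / y
    for (i in 1:50) {
        tri <- trigamma(x)
        dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
        x <- x + dif
        if (abs(dif) / x < 1e-10) break
    }
    x
}

#' Empirical-Bayes shrinkage of quasi-dispersions
#'
#' Moment-matches the log quasi-dispersions to the scaled-F model
#' `s2 ~ s0 * F(df, priorDF)`: the excess of the observed variance of
#' `log(s2)` over the sampling variance `trigamma(df/2)` determines the
#' prior df via the inverse trigamma; squeezed values are the df-weighted
#' combination `(df * s2 + priorDF * s0) / (df + priorDF)`. When the
#' observed spread does not exceed the sampling variance the prior df is
#' infinite and every value shrinks fully to the common `s0`.
#'
#' @param s2 raw quasi-dispersions (deviance / residual df).
#' @param df residual degrees of freedom (scalar).
#' @return list with `squeezed`, `priorDF`, `s0`.
#' @export
squeezeQuasiDispersions <- function(s2, df) {
    s2f <- pmax(s2, 1e-10)
    z <- log(s2f)
    ## identical inputs carry no sampling spread to moment-match: the
    ## common value is its own prior and shrinkage is a no-op
    if (length(s2) >= 2 && stats::var(z) < 1e-12)
        return(list(squeezed = s2, priorDF = Inf, s0 = s2[1]))
    e <- z - digamma(df / 2) + log(df / 2)
    evar <- stats::var(e) - trigamma(df / 2)
    if (length(s2) < 2 || !is.finite(evar) || evar <= 0) {
        s0 <- exp(mean(e))
        return(list(squeezed = rep(s0, length(s2)), priorDF = Inf, s0 = s0))
    }
    priorDF <- 2 * .trigammaInverse(evar)
    s0 <- exp(mean(e) + digamma(priorDF / 2) - log(priorDF / 2))
    squeezed <- (df * s2 + priorDF * s0) / (df + priorDF)
    list(squeezed = squeezed, priorDF = priorDF, s0 = s0)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment. `NaN`/`NA` p-values propagate as
#' `NA` and are excluded from the ranking.
#'
#' @param p numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return vector of BH-adjusted q-values.
#' @export
bhAdjust <- function(p) {
    ok <- !is.na(p)
    if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
    q <- rep(NA_real_, length(p))
    q[ok] <- stats::p.adjust(p[ok], method = "BH")
    q
}

#' Quasi-likelihood F-test for one contrast
#'
#' Fits the full NB GLM and the contrast-constrained null model at the
#' trended dispersions and forms, per miRNA,
#' `F = ((dev_null - dev_full) / df1) / s2_post` with the squeezed
#' quasi-dispersion `s2_post`; p-values come from the F distribution with
#' `(df1, priorDF + residDF)` degrees of freedom. The log2 fold-change is
#' the contrast applied to the fitted coefficients, divided by `log(2)`.
#'
#' @param x a [MiRNAExperiment-class] or count matrix.
#' @param design design matrix (one coefficient per condition cell).
#' @param contrast numeric contrast vector over the design coefficients
#'   (must be non-zero).
#' @param dispersions a [DispersionEstimates-class] from
#'   [estimateDispersions()] on the same counts/design.
#' @param offsets log effective library sizes (defaults as in
#'   [estimateDispersions()]).
#' @return a `DETable`: data.frame with columns `mirna_id`, `log2fc`,
#'   `avg_log2cpm`, `f_stat`, `df1`, `df2`, `p_value`, `q_value`.
#' @export
qlFTest <- function(x, design, contrast, dispersions, offsets = NULL) {
    cnt <- if (is(x, "MiRNAExperiment")) counts(x) else as.matrix(x)
    if (is.null(offsets)) {
        offsets <- if (is(x, "MiRNAExperiment") &&
                       "norm.factor" %in% colnames(colData(x)))
            effectiveLibOffsets(x) else log(colSums(cnt))
    }
    X <- as.matrix(design)
    contrast <- as.numeric(contrast)
    if (length(contrast) != ncol(X))
        stop("contrast length must equal the number of coefficients")
    if (all(contrast == 0)) stop("contrast vector must be non-zero")
    ## orthonormal basis of the coefficient subspace with contrast'beta = 0
    Q <- qr.Q(qr(cbind(contrast)), complete = TRUE)
    X0 <- X %*% Q[, -1, drop = FALSE]
    phi <- dispersions@trended
    full <- .fitManyNB(cnt, X, offsets, phi)
    null <- .fitManyNB(cnt, X0, offsets, phi)
    df1 <- 1
    s2 <- dispersions@quasiSqueezed
    fstat <- pmax(0, (null$deviance - full$deviance) / df1) / s2
    df2 <- dispersions@priorDF + dispersions@residDF
    pval <- if (is.finite(df2)) stats::pf(fstat, df1, df2, lower.tail = FALSE)
            else stats::pchisq(df1 * fstat, df1, lower.tail = FALSE)
    bad <- !(full$converged & null$converged)
    if (any(bad)) {
        warning(sum(bad), " miRNA fit(s) did not converge; p set to 1")
        pval[bad] <- 1
    }
    log2fc <- drop(full$coefficients %*% contrast) / log(2)
    ids <- rownames(cnt)
    if (is.null(ids)) ids <- paste0("row", seq_len(nrow(cnt)))
    data.frame(mirna_id = ids, log2fc = log2fc,
               avg_log2cpm = dispersions@aveLogCPM, f_stat = fstat,
               df1 = df1, df2 = df2, p_value = pval,
               q_value = bhAdjust(pval), row.names = NULL)
}

#' The six pairwise timepoint contrasts of the temporal analysis
#'
#' @param timepoints ordered timepoint labels (default D0, D13, D40, D75).
#' @return named list of contrast vectors over one-coefficient-per-timepoint
#'   designs, later minus earlier (e.g. `D13_vs_D0`).
#' @export
temporalContrasts <- function(timepoints = TIMEPOINTS) {
    k <- length(timepoints)
    out <- list()
    for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
        v <- numeric(k)
        v[j] <- 1; v[i] <- -1
        out[[paste0(timepoints[j], "_vs_", timepoints[i])]] <- v
    }
    out
}

#' Temporal differential expression within one region
#'
#' Subsets one genotype's samples of a region (the shared iPSC D0 baseline
#' is always included), fits a one-coefficient-per-timepoint NB GLM with the
#' shared dispersion estimates of that subset, and runs the quasi-likelihood
#' F-test for the six pairwise timepoint comparisons.
#'
#' @param x a normalized [MiRNAExperiment-class].
#' @param region `"dorsal"` or `"ventral"`.
#' @param genotype genotype analysed (default `"IC"`).
#' @return named list of six `DETable` data.frames (see [qlFTest()]).
#' @export
temporalDE <- function(x, region, genotype = "IC") {
    stopifnot(is(x, "MiRNAExperiment"), region %in% c("dorsal", "ventral"))
    cd <- colData(x)
    sel <- cd$genotype == genotype & cd$region %in% c("iPSC", region)
    sub <- x[, sel]
    tp <- factor(colData(sub)$timepoint, levels = TIMEPOINTS)
    tp <- droplevels(tp)
    if (nlevels(tp) < 2) stop("need at least two timepoints in region ", region)
    X <- stats::model.matrix(~ 0 + tp)
    colnames(X) <- levels(tp)
    offs <- effectiveLibOffsets(sub)
    disp <- estimateDispersions(sub, X, offs)
    ctr <- temporalContrasts(levels(tp))
    lapply(ctr, function(v) qlFTest(sub, X, v, disp, offs))
}

#' Per-timepoint RTT-vs-IC differential expression
#'
#' For each of the seven condition cells (iPSC D0 and each region x
#' organoid-timepoint combination), subsets the two genotype groups, fits a
#' two-coefficient genotype model with dispersions estimated on that subset,
#' and tests the RTT minus IC contrast. Fold-changes are signed RTT minus
#' IC, and BH adjustment is applied within each comparison separately.
#'
#' @param x a normalized [MiRNAExperiment-class].
#' @return named list of up to seven `DETable` data.frames, named
#'   `region_timepoint` (e.g. `iPSC_D0`, `dorsal_D40`). Cells lacking a
#'   genotype are skipped with a warning.
#' @export
genotypeDE <- function(x) {
    stopifnot(is(x, "MiRNAExperiment"))
    cells <- rbind(data.frame(region = "iPSC", timepoint = "D0"),
                   expand.grid(region = c("dorsal", "ventral"),
                               timepoint = c("D13", "D40", "D75"),
                               stringsAsFactors = FALSE))
    cd <- colData(x)
    out <- list()
    for (i in seq_len(nrow(cells))) {
        sel <- cd$region == cells$region[i] & cd$timepoint == cells$timepoint[i]
        nm <- paste(cells$region[i], cells$timepoint[i], sep = "_")
        sub <- x[, sel]
        gt <- colData(sub)$genotype
        if (length(unique(gt)) < 2 || min(table(gt)) < 2) {
            warning("comparison ", nm,
                    " skipped: both genotypes need >= 2 replicates")
            next
        }
        g <- factor(gt, levels = GENOTYPES)
        X <- stats::model.matrix(~ 0 + g)
        colnames(X) <- GENOTYPES
        offs <- effectiveLibOffsets(sub)
        disp <- estimateDispersions(sub, X, offs)
        out[[nm]] <- qlFTest(sub, X, c(-1, 1), disp, offs)  # RTT - IC
    }
    out
}
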