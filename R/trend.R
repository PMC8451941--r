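# Gaussian-process trend of binding change versus motif composition,
# single-site region selection, the greater-than-additive cooperativity
# test, and fold-change correlation against external contrasts.

rbfK <- function(x1, x2, ls, sigf2) {
    sigf2 * exp(-0.5 * outer(x1, x2, "-")^2 / ls^2)
}

# Negative log marginal likelihood of (ls, sigf2, sign2) on centred y.
gpNLML <- function(logp, x, yc) {
    ls <- exp(logp[1L]); sigf2 <- exp(logp[2L]); sign2 <- exp(logp[3L])
    n <- length(x)
    Kf <- rbfK(x, x, ls, sigf2) + diag(sign2, n)
    ch <- tryCatch(chol(Kf), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    a <- backsolve(ch, forwardsolve(t(ch), yc))
    0.5 * sum(yc * a) + sum(log(diag(ch))) + 0.5 * n * log(2 * pi)
}

#' Gaussian-process regression trend
#'
#' Exact GP regression with a squared-exponential (RBF) kernel plus
#' independent Gaussian noise, as used to display the smoothed trend of
#' (Z-scored) binding fold change against motif-variant composition. The
#' response is mean-centred internally; the posterior mean and the
#' standard deviation of the latent mean function are returned on a
#' prediction grid. Hyperparameters start from lengthscale = x-range / 5,
#' signal variance = var(y), noise variance = var(y) / 10 and, when
#' `optimise = TRUE`, are refined by marginal-likelihood maximisation
#' (L-BFGS-B on log parameters, `restarts` seeded restarts).
#'
#' If the kernel matrix is ill-conditioned, diagonal jitter is added in
#' decade steps from 1e-10 up to 1e-4 times the signal variance (recorded
#' in the fit), beyond which an error is raised.
#'
#' @param x,y finite numeric vectors (>= 5 points).
#' @param predX prediction grid (default: 100 equispaced points over the
#'   x-range).
#' @param optimise optimise hyperparameters (default `TRUE`).
#' @param lengthscale,sigf2,sign2 optional fixed/initial hyperparameters.
#' @param restarts optimiser restarts (default 3).
#' @param seed seed for the restart perturbations.
#' @return a [TrendFit-class].
#' @examples
#' set.seed(1)
#' x <- seq(0, 1, length.out = 30)
#' fit <- gpTrend(x, sin(2 * pi * x) + rnorm(30, sd = 0.1))
#' fit
#' @export
gpTrend <- function(x, y, predX = NULL, optimise = TRUE,
                    lengthscale = NULL, sigf2 = NULL, sign2 = NULL,
                    restarts = 3L, seed = 1L) {
    if (length(x) != length(y) || length(x) < 5L)
        stop("need >= 5 aligned (x, y) points")
    if (any(!is.finite(x)) || any(!is.finite(y)))
        stop("non-finite values in 'x' or 'y'")
    if (is.null(predX))
        predX <- seq(min(x), max(x), length.out = 100L)
    vy <- stats::var(y)
    if (vy == 0) vy <- 1e-12
    ls0 <- if (is.null(lengthscale)) max(diff(range(x)) / 5, 1e-8)
           else lengthscale
    sf0 <- if (is.null(sigf2)) vy else sigf2
    sn0 <- if (is.null(sign2)) vy / 10 else sign2
    mu <- mean(y)
    yc <- y - mu
    theta <- log(c(ls0, sf0, sn0))
    if (optimise) {
        best <- NULL
        withSeed(seed, {
            for (r in seq_len(restarts)) {
                init <- theta + if (r == 1L) 0 else stats::rnorm(3L, 0, 0.5)
                opt <- tryCatch(stats::optim(init, gpNLML, x = x, yc = yc,
                                             method = "L-BFGS-B",
                                             lower = theta - 8,
                                             upper = theta + 8),
                                error = function(e) NULL)
                if (!is.null(opt) &&
                    (is.null(best) || opt$value < best$value))
                    best <- opt
            }
        })
        if (!is.null(best)) theta <- best$par
    }
    ls <- exp(theta[1L]); sf2 <- exp(theta[2L]); sn2 <- exp(theta[3L])
    n <- length(x)
    jitter <- 0
    ch <- NULL
    for (j in c(0, 10^seq(-10, -4))) {
        Kf <- rbfK(x, x, ls, sf2) + diag(sn2 + j * sf2, n)
        ch <- tryCatch(chol(Kf), error = function(e) NULL)
        if (!is.null(ch)) { jitter <- j * sf2; break }
    }
    if (is.null(ch))
        stop("kernel matrix remains ill-conditioned after maximal jitter")
    a <- backsolve(ch, forwardsolve(t(ch), yc))
    Ks <- rbfK(predX, x, ls, sf2)
    postMean <- as.numeric(Ks %*% a) + mu
    V <- forwardsolve(t(ch), t(Ks))
    postVar <- pmax(sf2 - colSums(V^2), 0)
    logML <- -gpNLML(theta, x, yc)
    new("TrendFit", x = as.numeric(x), y = as.numeric(y),
        predX = as.numeric(predX), postMean = postMean,
        postSd = sqrt(postVar),
        kernelParams = c(lengthscale = ls, sigf2 = sf2, sign2 = sn2),
        logML = logML, jitter = jitter,
        meta = list(optimised = optimise, restarts = restarts, seed = seed,
                    centre = mu))
}

#' Regions harbouring exactly one half-site
#'
#' @param hits trimmed-half-site hits ([scanTrimmedHalfsite()]) at the
#'   configured mismatch level.
#' @param regionIds region ids to consider.
#' @return the ids of regions with exactly one hit.
#' @export
singleSiteRegions <- function(hits, regionIds) {
    counts <- table(factor(hits$region_id, levels = regionIds))
    regionIds[counts == 1L]
}

#' Greater-than-additive cooperativity test
#'
#' For aligned per-region log2 fold changes of two single depletions and
#' the double depletion, computes `delta = fc_double - (fc_1 + fc_2)`.
#' Under exact additivity on the log scale delta is centred at zero; a
#' greater-than-additive *loss* makes deltas negative. Tested with a
#' one-sided Wilcoxon signed-rank test of `median(delta) < 0`.
#'
#' @param fcE,fcN,fcEN aligned numeric log2FC vectors (single depletion of
#'   each factor, and the double depletion).
#' @param alternative direction of the test (default `"less"`, i.e.
#'   super-additive loss).
#' @return list: `delta`, `n`, `statistic`, `pvalue` (`NA` with
#'   `computable = FALSE` when fewer than 6 regions).
#' @export
additivityTest <- function(fcE, fcN, fcEN, alternative = "less") {
    stopifnot(length(fcE) == length(fcN), length(fcE) == length(fcEN))
    delta <- fcEN - (fcE + fcN)
    if (length(delta) < 6L)
        return(list(delta = delta, n = length(delta),
                    statistic = NA_real_, pvalue = NA_real_,
                    computable = FALSE))
    wt <- suppressWarnings(stats::wilcox.test(delta, mu = 0,
                                              alternative = alternative))
    list(delta = delta, n = length(delta),
         statistic = unname(wt$statistic), pvalue = wt$p.value,
         computable = TRUE)
}

#' Pearson correlation of fold changes across two contrasts
#'
#' Correlates per-gene fold changes of this study's contrast with an
#' external contrast over differentially expressed genes; the gene set is
#' the union (default) or intersection of the DE calls of the two
#' contrasts, intersected with the genes present in both fold-change
#' vectors.
#'
#' @param fcSelf,fcExternal named numeric vectors of log2 fold changes.
#' @param deSelf,deExternal character vectors of DE gene ids for each
#'   contrast.
#' @param rule `"union"` (default) or `"intersection"` of the DE calls.
#' @return list: `r`, `n`, `pvalue` (`computable = FALSE` with fewer than
#'   3 shared genes).
#' @export
foldchangeCorrelation <- function(fcSelf, fcExternal, deSelf = names(fcSelf),
                                  deExternal = names(fcExternal),
                                  rule = c("union", "intersection")) {
    rule <- match.arg(rule)
    de <- if (rule == "union") union(deSelf, deExternal)
          else intersect(deSelf, deExternal)
    g <- intersect(intersect(names(fcSelf), names(fcExternal)), de)
    if (length(g) < 3L)
        return(list(r = NA_real_, n = length(g), pvalue = NA_real_,
                    computable = FALSE))
    ct <- stats::cor.test(fcSelf[g], fcExternal[g], method = "pearson")
    list(r = unname(ct$estimate), n = length(g), pvalue = ct$p.value,
         computable = TRUE)
}
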