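# Negative-binomial differential binding / expression test.
#
# Self-contained NB Wald test in the spirit of the count-based
# differential tools this field uses: median-of-ratios size factors,
# per-unit method-of-moments dispersion shrunk halfway towards a trended
# mean-dispersion fit, an NB GLM with fixed dispersion, a Wald test on the
# condition coefficient with t-reference small-sample calibration, and BH
# correction. Declared pluggable: any function with the same contract can
# replace it downstream.

#' Median-of-ratios size factors
#'
#' Size factors by the median-of-ratios method when at least two samples
#' and some all-positive rows exist, otherwise total-count factors; both
#' are rescaled to geometric mean 1.
#'
#' @param counts raw count matrix (units x samples).
#' @return named numeric vector of size factors.
#' @export
normFactors <- function(counts) {
    counts <- as.matrix(counts)
    sf <- NULL
    if (ncol(counts) >= 2L) {
        pos <- rowSums(counts > 0) == ncol(counts)
        if (any(pos)) {
            lg <- log(counts[pos, , drop = FALSE])
            ref <- rowMeans(lg)
            sf <- exp(apply(lg - ref, 2L, stats::median))
        }
    }
    if (is.null(sf)) {
        cs <- colSums(counts)
        if (any(cs == 0)) stop("cannot compute size factors: empty sample")
        sf <- cs
    }
    sf <- sf / exp(mean(log(sf)))
    stats::setNames(sf, colnames(counts))
}

# Method-of-moments dispersion per unit, on size-factor-normalised counts,
# using within-condition variances. Returns raw (possibly <= 0) values.
momDispersion <- function(q, conditions) {
    mu <- rowMeans(q)
    condLevels <- unique(conditions)
    v <- matrix(NA_real_, nrow(q), length(condLevels))
    for (i in seq_along(condLevels)) {
        qc <- q[, conditions == condLevels[i], drop = FALSE]
        if (ncol(qc) >= 2L) v[, i] <- apply(qc, 1L, stats::var)
    }
    s2 <- rowMeans(v, na.rm = TRUE)
    (s2 - mu) / mu^2
}

# Trended dispersion fit a0 + a1/mu on units with positive raw estimates.
trendDispersion <- function(alphaRaw, mu) {
    use <- which(is.finite(alphaRaw) & alphaRaw > 0 & mu > 0)
    if (length(use) >= 10L) {
        fit <- stats::lm(alphaRaw[use] ~ I(1 / mu[use]))
        a0 <- max(stats::coef(fit)[1L], 1e-6)
        a1 <- max(stats::coef(fit)[2L], 0)
    } else {
        a0 <- max(mean(alphaRaw[use]), 0.01)
        a1 <- 0
    }
    pmax(a0 + a1 / pmax(mu, 1e-8), 1e-6)
}

#' Negative-binomial Wald test for differential binding or expression
#'
#' Compares two conditions of a [BindingExperiment-class] (optionally
#' restricted to one TF) unit by unit. Dispersion is estimated per unit by
#' the method of moments with variance `mu + alpha * mu^2` and shrunk with
#' weight `trendWeight` towards a trended `a0 + a1/mu` fit (pooled
#' trend-only dispersion, flagged, when a condition has a single
#' replicate). Each unit is then fit with an NB log-link GLM at fixed
#' dispersion, offset by log size factors, and the condition coefficient
#' is tested with a Wald statistic referred to a t distribution with
#' (samples - 2) degrees of freedom — the small-sample calibration that
#' keeps the type-I error near nominal with triplicate designs. P-values
#' are BH-adjusted.
#'
#' @param be a [BindingExperiment-class] with raw counts.
#' @param contrast length-2 character: `c(reference, alternative)`
#'   condition; `log2fc > 0` means higher in the alternative.
#' @param tf optional TF name to subset samples.
#' @param fdrThreshold threshold for the `call` column (default 0.05).
#' @param trendWeight weight of the trended dispersion in the shrunk
#'   estimate (default 0.5).
#' @param sizeFactors `"median-ratio"` (default; assumes most units are
#'   unchanged between conditions), `"libsize"` (use the recorded library
#'   sizes; appropriate when a global occupancy shift is plausible) or
#'   `"total"` (column sums). All are rescaled to geometric mean 1.
#' @return data.frame with `unit_id`, `baseMean`, `log2fc`, `se`, `stat`,
#'   `pvalue`, `fdr`, `call` (`up`/`down`/`ns`) and `flag`
#'   (`ok`/`allzero`/`pooled_dispersion`), rows in input unit order.
#' @examples
#' sim <- simulateCounts(list(region_class = setNames(rep(1, 50),
#'                            paste0("r", 1:50))),
#'                       sampleSheet("Oct4", c("pp", "dEN"), 3),
#'                       effects = plantedEffects(1, 0), seed = 1)
#' head(differentialTest(sim, c("pp", "dEN")))
#' @export
#' @importFrom MASS negative.binomial
differentialTest <- function(be, contrast, tf = NULL, fdrThreshold = 0.05,
                             trendWeight = 0.5,
                             sizeFactors = c("median-ratio", "libsize",
                                             "total")) {
    sizeFactors <- match.arg(sizeFactors)
    stopifnot(methods::is(be, "BindingExperiment"), length(contrast) == 2L)
    cd <- as.data.frame(colData(be))
    sel <- cd$condition %in% contrast
    if (!is.null(tf)) sel <- sel & cd$tf == tf
    if (!any(sel)) stop("contrast/tf selects no samples")
    cnt <- assay(be, "counts")[, sel, drop = FALSE]
    cond <- factor(cd$condition[sel], levels = contrast)
    if (nlevels(droplevels(cond)) != 2L)
        stop("both contrast conditions need samples")
    reps <- table(cond)
    pooledOnly <- any(reps < 2L)
    sf <- switch(sizeFactors,
        "median-ratio" = normFactors(cnt),
        "libsize" = {
            ls <- librarySizes(be)[colnames(cnt)]
            stats::setNames(ls / exp(mean(log(ls))), colnames(cnt))
        },
        "total" = {
            cs <- colSums(cnt)
            stats::setNames(cs / exp(mean(log(cs))), colnames(cnt))
        })
    q <- sweep(cnt, 2L, sf, "/")
    mu <- rowMeans(q)
    alphaRaw <- if (pooledOnly) rep(NA_real_, nrow(q))
                else momDispersion(q, as.character(cond))
    alphaTrend <- if (pooledOnly) {
        # no replicates to estimate per-unit dispersion: single pooled value
        rep(max(mean(pmax((apply(q, 1L, stats::var) - mu) / mu^2, 0),
                     na.rm = TRUE), 0.01), nrow(q))
    } else trendDispersion(alphaRaw, mu)
    alpha <- if (pooledOnly) alphaTrend
             else (1 - trendWeight) * pmax(alphaRaw, 0) +
                  trendWeight * alphaTrend
    alpha <- pmax(alpha, 1e-6)
    off <- log(sf)
    xAlt <- as.integer(cond == contrast[2L])
    df <- max(length(cond) - 2L, 1L)
    n <- nrow(cnt)
    log2fc <- se <- stat <- pval <- numeric(n)
    flag <- rep(if (pooledOnly) "pooled_dispersion" else "ok", n)
    saturated <- length(cond) <= 2L
    for (i in seq_len(n)) {
        y <- cnt[i, ]
        if (all(y == 0)) {
            log2fc[i] <- 0; se[i] <- NA_real_; stat[i] <- 0; pval[i] <- 1
            flag[i] <- "allzero"
            next
        }
        if (saturated) {
            # no residual degrees of freedom for a GLM: analytic Wald on
            # the group means with delta-method variance (1/mu + alpha)/m
            qi <- y / sf
            m1 <- max(mean(qi[xAlt == 0L]), 0.25)
            m2 <- max(mean(qi[xAlt == 1L]), 0.25)
            v <- (1 / m1 + alpha[i]) / sum(xAlt == 0L) +
                 (1 / m2 + alpha[i]) / sum(xAlt == 1L)
            log2fc[i] <- log2(m2 / m1)
            se[i] <- sqrt(v) / log(2)
            stat[i] <- log(m2 / m1) / sqrt(v)
            pval[i] <- 2 * stats::pnorm(-abs(stat[i]))
            next
        }
        cf <- tryCatch({
            fit <- suppressWarnings(stats::glm(
                y ~ xAlt + offset(off),
                family = MASS::negative.binomial(theta = 1 / alpha[i])))
            suppressWarnings(summary(fit)$coefficients)
        }, error = function(e) matrix(numeric(), 0L, 0L))
        if (nrow(cf) < 2L || ncol(cf) < 2L || !is.finite(cf[2L, 2L])) {
            log2fc[i] <- 0; se[i] <- NA_real_; stat[i] <- 0; pval[i] <- 1
            flag[i] <- "degenerate"
            next
        }
        log2fc[i] <- cf[2L, 1L] / log(2)
        se[i] <- cf[2L, 2L] / log(2)
        stat[i] <- cf[2L, 1L] / cf[2L, 2L]
        pval[i] <- 2 * stats::pt(-abs(stat[i]), df = df)
    }
    fdr <- stats::p.adjust(pval, method = "BH")
    call <- rep("ns", n)
    call[fdr < fdrThreshold & log2fc > 0] <- "up"
    call[fdr < fdrThreshold & log2fc < 0] <- "down"
    data.frame(unit_id = rownames(cnt), baseMean = mu, log2fc = log2fc,
               se = se, stat = stat, pvalue = pval, fdr = fdr, call = call,
               flag = flag, stringsAsFactors = FALSE, row.names = NULL)
}
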