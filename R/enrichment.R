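# The two bespoke enrichment statistics: motif-pair distance enrichment
# against a randomised within-region background with Poisson right-tail
# p-values, and the hypergeometric proximity scan of differentially
# expressed genes around region classes over a distance grid.

PCLAMP <- 1e-300

#' Keep hits scoring strictly above the median of their motif's hit set
#'
#' @param hits hit data.frame with `score` and `motif_name`.
#' @return the subset with `score > median(score)` computed per motif
#'   (empty when all scores of a motif are equal).
#' @export
filterAboveMedian <- function(hits) {
    if (nrow(hits) == 0L) return(hits)
    if (anyNA(hits$score)) stop("scores are required for the median filter")
    keep <- unlist(lapply(split(seq_len(nrow(hits)), hits$motif_name),
                          function(i)
                              i[hits$score[i] > stats::median(hits$score[i])]))
    hits[sort(keep), , drop = FALSE]
}

hitCentres <- function(hits) hits$offset + floor(hits$width / 2)

# All intra-region A-B centre distances. When A and B are the same set,
# self-pairs (the identical hit playing both roles) are excluded; distinct
# overlapping hits are kept.
pairDistances <- function(hitsA, hitsB) {
    if (nrow(hitsA) == 0L || nrow(hitsB) == 0L) return(numeric())
    keyA <- paste(hitsA$region_id, hitsA$offset, hitsA$strand,
                  hitsA$motif_name, hitsA$width)
    keyB <- paste(hitsB$region_id, hitsB$offset, hitsB$strand,
                  hitsB$motif_name, hitsB$width)
    cA <- hitCentres(hitsA); cB <- hitCentres(hitsB)
    out <- numeric()
    common <- intersect(unique(hitsA$region_id), unique(hitsB$region_id))
    for (rid in common) {
        ia <- which(hitsA$region_id == rid)
        ib <- which(hitsB$region_id == rid)
        d <- abs(outer(cA[ia], cB[ib], "-"))
        self <- outer(keyA[ia], keyB[ib], "==")
        out <- c(out, d[!self])
    }
    out
}

distBreaks <- function(binWidth, maxDist) seq(0, maxDist, by = binWidth)

histCounts <- function(d, breaks) {
    d <- d[d >= breaks[1L] & d < breaks[length(breaks)]]
    tabulate(findInterval(d, breaks), nbins = length(breaks) - 1L)
}

#' Histogram of motif-pair centre distances within regions
#'
#' For every region, every pair of one A-hit and one B-hit contributes the
#' absolute distance between the motif centres
#' (`offset + floor(width / 2)`); pairs never cross regions. Distances are
#' binned into `[0, binWidth), [binWidth, 2 binWidth), ...` up to
#' `maxDist` (larger distances are dropped).
#'
#' @param hitsA,hitsB hit data.frames (see [scanConsensus()]).
#' @param binWidth bin width in bp (default 10).
#' @param maxDist histogram upper limit in bp (default 500).
#' @return list with `mids` (bin midpoints), `breaks` and `counts`.
#' @export
pairDistanceCounts <- function(hitsA, hitsB, binWidth = 10, maxDist = 500) {
    if (binWidth < 1) stop("'binWidth' must be >= 1")
    breaks <- distBreaks(binWidth, maxDist)
    d <- pairDistances(hitsA, hitsB)
    list(mids = utils::head(breaks, -1L) + binWidth / 2, breaks = breaks,
         counts = histCounts(d, breaks))
}

#' Expected pair-distance histogram from a randomised background
#'
#' Re-draws each hit's position uniformly among the placements that fit
#' inside its own region, preserving the per-region hit counts and strand
#' labels, and averages the resulting pair-distance histogram over
#' `nShuffles` shuffles. Hits in regions shorter than their motif are
#' dropped with a warning.
#'
#' @inheritParams pairDistanceCounts
#' @param regionWidths named integer vector of region widths (bp) covering
#'   every region that has hits.
#' @param nShuffles number of shuffles (default 100).
#' @param seed integer seed; the result is deterministic given it.
#' @return list with `mids`, `breaks`, `expected` (mean counts per bin)
#'   and `nShuffles`.
#' @export
randomisedBackground <- function(hitsA, hitsB, regionWidths,
                                 nShuffles = 100L, seed = 1L,
                                 binWidth = 10, maxDist = 500) {
    if (nShuffles < 1L) stop("'nShuffles' must be >= 1")
    breaks <- distBreaks(binWidth, maxDist)
    dropUnplaceable <- function(h) {
        w <- regionWidths[h$region_id]
        if (anyNA(w)) stop("region widths missing for some hits")
        bad <- h$width > w
        if (any(bad)) {
            warning(sum(bad), " hit(s) in regions shorter than the motif ",
                    "were skipped")
            h <- h[!bad, , drop = FALSE]
        }
        h
    }
    hitsA <- dropUnplaceable(hitsA)
    hitsB <- dropUnplaceable(hitsB)
    maxOffA <- regionWidths[hitsA$region_id] - hitsA$width
    maxOffB <- regionWidths[hitsB$region_id] - hitsB$width
    acc <- numeric(length(breaks) - 1L)
    withSeed(seed, {
        for (s in seq_len(nShuffles)) {
            a <- hitsA
            b <- hitsB
            a$offset <- floor(stats::runif(nrow(a), 0, maxOffA + 1))
            b$offset <- floor(stats::runif(nrow(b), 0, maxOffB + 1))
            acc <- acc + histCounts(pairDistances(a, b), breaks)
        }
    })
    list(mids = utils::head(breaks, -1L) + binWidth / 2, breaks = breaks,
         expected = acc / nShuffles, nShuffles = nShuffles)
}

#' Poisson right-tail enrichment over a distance histogram
#'
#' Per bin, `p = P(X >= observed)` with `X ~ Poisson(expected)`. A bin
#' with zero expectation has `p = 1` when nothing was observed and `p = 0`
#' (flagged degenerate in `meta`) otherwise. `-log10(p)` is computed after
#' clamping underflowed p-values at 1e-300; the clamp is recorded.
#'
#' @param observed,expected aligned non-negative vectors.
#' @param grid distances labelling the bins (default `seq_along`).
#' @param meta extra provenance fields merged into the curve metadata.
#' @return an [EnrichmentCurve-class] with `meta$test = "poisson"`.
#' @examples
#' poissonEnrichment(c(0, 10), c(2, 5), grid = c(5, 15))
#' @export
poissonEnrichment <- function(observed, expected, grid = seq_along(observed),
                              meta = list()) {
    if (length(observed) != length(expected))
        stop("'observed' and 'expected' must be aligned")
    if (any(observed < 0) || any(expected < 0))
        stop("'observed' and 'expected' must be non-negative")
    p <- stats::ppois(observed - 1, lambda = expected, lower.tail = FALSE)
    degen <- expected == 0 & observed > 0
    p[degen] <- 0
    p[expected == 0 & observed == 0] <- 1
    nl <- -log10(pmax(p, PCLAMP))
    new("EnrichmentCurve", grid = as.numeric(grid),
        observed = as.numeric(observed), expected = as.numeric(expected),
        pvalue = p, neglog10p = nl,
        meta = c(list(test = "poisson", clamp = PCLAMP,
                      degenerate = which(degen)), meta))
}

#' Motif-pair spacing enrichment curve
#'
#' Convenience wrapper chaining [pairDistanceCounts()],
#' [randomisedBackground()] and [poissonEnrichment()].
#'
#' @inheritParams randomisedBackground
#' @return an [EnrichmentCurve-class] over bin midpoints.
#' @export
pairDistanceEnrichment <- function(hitsA, hitsB, regionWidths,
                                   nShuffles = 100L, seed = 1L,
                                   binWidth = 10, maxDist = 500) {
    obs <- pairDistanceCounts(hitsA, hitsB, binWidth, maxDist)
    bg <- randomisedBackground(hitsA, hitsB, regionWidths, nShuffles, seed,
                               binWidth, maxDist)
    poissonEnrichment(obs$counts, bg$expected, grid = obs$mids,
                      meta = list(n_shuffles = nShuffles, seed = seed,
                                  bin_width = binWidth, max_dist = maxDist))
}

# Distance from each TSS to the nearest region of a set: 0 when the TSS
# (0-based) lies inside a region, otherwise the number of bases separating
# it from the closest region edge (a TSS on the base just past an edge is
# 1 bp away). Inf when the chromosome has no region.
tssRegionDistance <- function(genes, regions) {
    out <- rep(Inf, nrow(genes))
    if (length(regions) == 0L) return(out)
    rchr <- as.character(GenomicRanges::seqnames(regions))
    rs0 <- GenomicRanges::start(regions) - 1L  # 0-based inclusive
    re0 <- GenomicRanges::end(regions)         # 0-based exclusive
    for (chr in unique(genes$chrom)) {
        gi <- which(genes$chrom == chr)
        ri <- which(rchr == chr)
        if (!length(ri)) next
        tss <- genes$tss[gi]
        d <- rep(Inf, length(gi))
        for (j in ri) {
            dj <- pmax(0, rs0[j] - tss, tss - (re0[j] - 1L))
            d <- pmin(d, dj)
        }
        out[gi] <- d
    }
    out
}

#' Genes whose TSS lies within x bp of a region set
#'
#' A gene is included iff the minimum distance from its TSS to any region
#' of the set is `<= x` (0 when the TSS falls inside a region; same
#' chromosome required).
#'
#' @param genes gene annotation data.frame (`gene_id`, `chrom`, `tss`).
#' @param regions a `GRanges`.
#' @param x distance in bp (>= 0).
#' @return character vector of gene ids.
#' @export
genesWithin <- function(genes, regions, x) {
    if (x < 0) stop("'x' must be >= 0")
    genes$gene_id[tssRegionDistance(genes, regions) <= x]
}

#' Default proximity distance grid
#'
#' @param n number of points (default 50).
#' @param from,to range in bp (default 1 to 1e6).
#' @return `n` log-spaced distances, rounded to integer bp, unique.
#' @export
proximityGrid <- function(n = 50L, from = 1, to = 1e6) {
    unique(round(10^seq(log10(from), log10(to), length.out = n)))
}

#' Hypergeometric proximity enrichment of DE genes around regions
#'
#' At each distance `x` of the grid: `N` = number of genes in the
#' universe, `K` = genes within `x` of the region set, `n` = DE genes,
#' `k` = DE genes within `x`; the p-value is the hypergeometric right
#' tail `P(X >= k)`. The expected count is `n * K / N`.
#'
#' @param deGenes character vector of DE gene ids (must all be in the
#'   universe).
#' @param genes gene universe annotation data.frame (`gene_id`, `chrom`,
#'   `tss`); by design the universe is the set of genes passing the
#'   expression count filter.
#' @param regions `GRanges` of the region set (e.g. one occupancy class).
#' @param grid ascending distances in bp (default [proximityGrid()]).
#' @return an [EnrichmentCurve-class] (`observed` = k, `expected` =
#'   nK/N, `meta$test = "hypergeometric"`, plus `N`, `n` and `K` per
#'   distance in `meta`).
#' @export
proximityEnrichmentScan <- function(deGenes, genes, regions,
                                    grid = proximityGrid()) {
    deGenes <- unique(deGenes)
    if (!all(deGenes %in% genes$gene_id))
        stop("consistency error: DE gene(s) absent from the gene universe")
    if (is.unsorted(grid)) stop("'grid' must be ascending")
    N <- nrow(genes)
    n <- length(deGenes)
    d <- tssRegionDistance(genes, regions)
    isDe <- genes$gene_id %in% deGenes
    K <- vapply(grid, function(x) sum(d <= x), 0L)
    k <- vapply(grid, function(x) sum(d <= x & isDe), 0L)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    nl <- -log10(pmax(p, PCLAMP))
    new("EnrichmentCurve", grid = as.numeric(grid), observed = as.numeric(k),
        expected = n * K / N, pvalue = p, neglog10p = nl,
        meta = list(test = "hypergeometric", clamp = PCLAMP, N = N, n = n,
                    K = K))
}
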