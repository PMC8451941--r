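# Peak-set logic (replicate reproducibility, merging, blacklist, Venn)
# and count normalisation / filtering.

#' Replicate-reproducible peaks
#'
#' Keeps the genomic stretches covered by peaks in at least
#' `minReplicates` of the supplied replicate peak sets and reports one
#' region per such maximal stretch (the "core"): the union-span of all
#' replicate peaks overlapping that core. Core coordinates are kept in
#' `mcols()` as `core_start`/`core_end` (1-based closed); spans of nearby
#' cores may overlap.
#'
#' @param replicateSets a `GRangesList` or list of `GRanges`, one per
#'   replicate.
#' @param minReplicates minimum number of replicates that must cover a
#'   base for it to be retained (`1` gives the plain union).
#' @return a `GRanges` of union-spans, reduced, with core coordinates.
#' @examples
#' gr <- function(s, e) GenomicRanges::GRanges("chr1",
#'                                             IRanges::IRanges(s, e))
#' reproduciblePeaks(list(gr(1, 100), gr(51, 150), gr(61, 90)), 3)
#' @export
#' @importFrom GenomicRanges GRangesList coverage reduce findOverlaps
#'   granges
#' @importFrom IRanges slice subsetByOverlaps
#' @importFrom S4Vectors queryHits subjectHits
reproduciblePeaks <- function(replicateSets, minReplicates) {
    if (length(replicateSets) == 0L)
        stop("at least one replicate peak set is required")
    if (minReplicates < 1L || minReplicates > length(replicateSets))
        stop("'minReplicates' must be in 1..number of replicate sets")
    all <- unlist(GenomicRanges::GRangesList(lapply(replicateSets,
                                                    GenomicRanges::granges)),
                  use.names = FALSE)
    if (length(all) == 0L) return(GenomicRanges::GRanges())
    cov <- GenomicRanges::coverage(all)
    cores <- GenomicRanges::GRanges(IRanges::slice(cov,
                                                   lower = minReplicates,
                                                   rangesOnly = TRUE))
    if (length(cores) == 0L) return(cores)
    ov <- GenomicRanges::findOverlaps(cores, all)
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    spanStart <- GenomicRanges::start(cores)
    spanEnd <- GenomicRanges::end(cores)
    mn <- tapply(GenomicRanges::start(all)[sh], qh, min)
    mx <- tapply(GenomicRanges::end(all)[sh], qh, max)
    i <- as.integer(names(mn))
    spanStart[i] <- pmin(spanStart[i], as.integer(mn))
    spanEnd[i] <- pmax(spanEnd[i], as.integer(mx))
    out <- GenomicRanges::GRanges(GenomicRanges::seqnames(cores),
                                  IRanges::IRanges(spanStart, spanEnd))
    mcols(out)$core_start <- GenomicRanges::start(cores)
    mcols(out)$core_end <- GenomicRanges::end(cores)
    out
}

#' Merge per-factor peak sets into shared regions with provenance flags
#'
#' Overlapping peaks across the input sets are merged into single regions;
#' each output region carries one logical column per input set saying
#' whether that set contributed a peak (the cross-tabulation of these
#' flags is the Venn diagram of co-binding).
#'
#' @param sets named list of `GRanges` (names become flag columns;
#'   unnamed sets are called set1, set2, ...).
#' @return a reduced `GRanges` with one logical `mcols()` column per set.
#' @seealso [vennCounts()]
#' @export
#' @importFrom IRanges overlapsAny
mergePeakSets <- function(sets) {
    if (is.null(names(sets)) || any(!nzchar(names(sets))))
        names(sets) <- paste0("set", seq_along(sets))
    all <- unlist(GenomicRanges::GRangesList(lapply(sets,
                                                    GenomicRanges::granges)),
                  use.names = FALSE)
    merged <- GenomicRanges::reduce(all)
    for (nm in names(sets))
        mcols(merged)[[nm]] <- IRanges::overlapsAny(merged, sets[[nm]])
    merged
}

#' Venn counts from merged-region provenance flags
#'
#' @param merged output of [mergePeakSets()].
#' @return a data.frame with one row per flag combination and a `count`
#'   column.
#' @export
vennCounts <- function(merged) {
    flags <- as.data.frame(mcols(merged))
    flags <- flags[vapply(flags, is.logical, TRUE)]
    agg <- stats::aggregate(list(count = rep(1L, nrow(flags))), flags, sum)
    agg[do.call(order, agg[colnames(flags)]), , drop = FALSE]
}

#' Remove regions overlapping a blacklist
#'
#' Drops any region overlapping any blacklist interval by at least 1 bp.
#'
#' @param regions a `GRanges`.
#' @param blacklist a `GRanges` of excluded intervals (may be empty).
#' @return the filtered `GRanges`.
#' @export
excludeBlacklist <- function(regions, blacklist) {
    if (length(blacklist) == 0L) return(regions)
    IRanges::subsetByOverlaps(regions, blacklist, invert = TRUE)
}

#' Library-size normalisation (reads per million / per ten million)
#'
#' Adds a `norm` assay with `count / lib_size * scale` and records the
#' normalisation state; raw counts are kept. Normalising an already
#' normalised object is an error.
#'
#' @param be a [BindingExperiment-class].
#' @param scale `"per-million"` (1e6) or `"per-ten-million"` (1e7).
#' @return the `BindingExperiment` with assay `"norm"`.
#' @export
normaliseCounts <- function(be, scale = c("per-million", "per-ten-million")) {
    scale <- match.arg(scale)
    if (isNormalised(be))
        stop("object is already normalised (", metadata(be)$scale, ")")
    ls <- librarySizes(be)
    if (any(ls <= 0)) stop("zero or negative library size")
    k <- if (scale == "per-million") 1e6 else 1e7
    SummarizedExperiment::assay(be, "norm") <-
        sweep(assay(be, "counts"), 2L, ls, "/") * k
    metadata(be)$normalised <- TRUE
    metadata(be)$scale <- scale
    validObject(be)
    be
}

#' Normalised values accessor
#'
#' @param be a normalised [BindingExperiment-class].
#' @return the `norm` assay matrix.
#' @export
normValues <- function(be) {
    if (!isNormalised(be)) stop("object has not been normalised yet")
    assay(be, "norm")
}

#' Z-score a vector of fold changes
#'
#' `(x - mean(x)) / sd(x)` with the sample (n-1) standard deviation.
#'
#' @param x numeric vector of (log2) fold changes, length >= 2.
#' @return z-scored vector.
#' @export
zscoreFoldchanges <- function(x) {
    if (length(x) < 2L) stop("need at least 2 values")
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) stop("zero variance: z-scores undefined")
    (x - mean(x)) / s
}

#' Differential-expression call filter
#'
#' Applies the expression filtering rules: a unit is kept iff (i) there is
#' at least one condition in which **all** replicates have at least
#' `minCount` raw counts, (ii) the absolute linear fold change is strictly
#' greater than `fcThreshold`, and (iii) FDR is strictly below
#' `fdrThreshold`. Direction is taken from the sign of `log2fc`.
#'
#' @param results data.frame with columns `unit_id`, `log2fc`, `fdr`.
#' @param counts raw count matrix (rows matching `results$unit_id`).
#' @param conditions condition label per column of `counts`.
#' @param minCount count rule threshold (default 20).
#' @param fcThreshold linear fold-change threshold (default 1.5, strict).
#' @param fdrThreshold FDR threshold (default 0.01, strict).
#' @return the surviving subset of `results` with a `direction` column
#'   (`up`/`down`).
#' @export
deFilter <- function(results, counts, conditions, minCount = 20,
                     fcThreshold = 1.5, fdrThreshold = 0.01) {
    stopifnot(all(c("unit_id", "log2fc", "fdr") %in% colnames(results)),
              ncol(counts) == length(conditions))
    cnt <- counts[match(results$unit_id, rownames(counts)), , drop = FALSE]
    if (anyNA(cnt))
        stop("raw counts missing for some units in 'results'")
    passCount <- rep(FALSE, nrow(results))
    for (cond in unique(conditions)) {
        cc <- cnt[, conditions == cond, drop = FALSE]
        passCount <- passCount | apply(cc >= minCount, 1L, all)
    }
    keep <- passCount & (2^abs(results$log2fc) > fcThreshold) &
        (results$fdr < fdrThreshold)
    out <- results[keep, , drop = FALSE]
    out$direction <- ifelse(out$log2fc > 0, "up", "down")
    out
}
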