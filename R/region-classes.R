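# Occupancy dependence classes: max-normalised occupancy matrix, seeded
# K-means with k-means++ restarts, deterministic label numbering, and
# enrichment-driven choice of k.

#' Mean normalised occupancy per (TF, condition)
#'
#' Collapses a normalised [BindingExperiment-class] to a region x
#' (TF, condition) matrix of replicate-mean normalised binding, the input
#' to [maxNormalise()] and clustering.
#'
#' @param be a normalised `BindingExperiment`.
#' @param tfs TFs to include (default: all, in first-appearance order).
#' @param conditions conditions to include (default: all).
#' @return numeric matrix with columns named `"TF.condition"`.
#' @export
occupancyMatrix <- function(be, tfs = NULL, conditions = NULL) {
    cd <- as.data.frame(colData(be))
    if (is.null(tfs)) tfs <- unique(cd$tf)
    if (is.null(conditions)) conditions <- unique(cd$condition)
    nv <- normValues(be)
    cols <- list()
    for (tf in tfs) for (cond in conditions) {
        sel <- cd$tf == tf & cd$condition == cond
        if (!any(sel)) stop("no samples for ", tf, " / ", cond)
        cols[[paste(tf, cond, sep = ".")]] <-
            rowMeans(nv[, sel, drop = FALSE])
    }
    do.call(cbind, cols)
}

#' Max-normalise occupancy rows per TF
#'
#' For each region and TF, divides the occupancy values across conditions
#' by their maximum, so the condition with maximal binding is set to one.
#' Regions where a TF shows no signal in any condition (max = 0) are set
#' to all zeros for that TF and flagged.
#'
#' @param occ matrix from [occupancyMatrix()], columns `"TF.condition"`.
#' @return matrix of the same shape with values in \[0, 1\] and an
#'   attribute `flagged`: a logical matrix (region x TF) marking zero
#'   rows.
#' @export
maxNormalise <- function(occ) {
    cn <- colnames(occ)
    tfOf <- sub("\\..*$", "", cn)
    tfs <- unique(tfOf)
    out <- occ
    flagged <- matrix(FALSE, nrow(occ), length(tfs),
                      dimnames = list(rownames(occ), tfs))
    for (tf in tfs) {
        j <- which(tfOf == tf)
        mx <- do.call(pmax, as.data.frame(occ[, j, drop = FALSE]))
        zero <- mx <= 0
        mx[zero] <- 1
        out[, j] <- occ[, j, drop = FALSE] / mx
        out[zero, j] <- 0
        flagged[, tf] <- zero
    }
    attr(out, "flagged") <- flagged
    out
}

# k-means++ seeding (Arthur & Vassilvitskii): iteratively pick centres
# with probability proportional to squared distance to the nearest centre.
kmeansPP <- function(X, k) {
    n <- nrow(X)
    centers <- matrix(NA_real_, k, ncol(X))
    i <- sample.int(n, 1L)
    centers[1L, ] <- X[i, ]
    d2 <- rowSums(sweep(X, 2L, centers[1L, ])^2)
    if (k >= 2L) for (j in 2:k) {
        if (all(d2 == 0)) i <- sample.int(n, 1L)
        else i <- sample.int(n, 1L, prob = d2)
        centers[j, ] <- X[i, ]
        d2 <- pmin(d2, rowSums(sweep(X, 2L, centers[j, ])^2))
    }
    centers
}

#' K-means occupancy classes
#'
#' Euclidean K-means on the max-normalised occupancy matrix, best of
#' `nInit` k-means++ seeded Lloyd runs by within-cluster sum of squares.
#' Labels are renumbered deterministically by increasing cluster mean over
#' the `orderBy` columns (by default, the columns of the double-depletion
#' condition), so class 1 shows the strongest loss; this makes the
#' numbering invariant to initialisation permutations.
#'
#' @param occ numeric region x feature matrix (rownames = region ids).
#' @param k number of classes (>= 2, <= number of distinct rows).
#' @param seed integer seed controlling all initialisations.
#' @param nInit number of restarts (default 10).
#' @param maxIter Lloyd iteration cap per restart (default 300).
#' @param orderBy columns used for label renumbering; default: columns
#'   whose name contains the double-depletion tag `"dEN"`, else all.
#' @return list with `assignment` (data.frame `region_id`, `class`),
#'   `centers`, `withinss` (total), `initss` (objective of the winning
#'   initialisation, always >= `withinss`).
#' @export
kmeansClasses <- function(occ, k, seed = 1L, nInit = 10L, maxIter = 300L,
                          orderBy = NULL) {
    if (k < 2L) stop("'k' must be at least 2")
    ndist <- nrow(unique(occ))
    if (k > ndist)
        stop("degeneracy error: k exceeds the number of distinct rows (",
             ndist, ")")
    best <- NULL
    withSeed(seed, {
        for (r in seq_len(nInit)) {
            ctr <- kmeansPP(occ, k)
            # duplicate seeded centres would make kmeans() error out
            if (anyDuplicated(ctr)) next
            km <- suppressWarnings(stats::kmeans(occ, centers = ctr,
                                                 iter.max = maxIter,
                                                 algorithm = "Lloyd"))
            init <- sum(vapply(seq_len(nrow(occ)), function(i)
                min(colSums((t(ctr) - occ[i, ])^2)), 0))
            if (is.null(best) || km$tot.withinss < best$km$tot.withinss)
                best <- list(km = km, initss = init)
        }
    })
    if (is.null(best)) stop("k-means failed: no valid initialisation")
    km <- best$km
    if (is.null(orderBy)) {
        orderBy <- grep("dEN", colnames(occ), value = TRUE)
        if (!length(orderBy)) orderBy <- colnames(occ)
    }
    sel <- km$centers[, orderBy, drop = FALSE]
    ord <- order(rowMeans(sel))
    relabel <- integer(k)
    relabel[ord] <- seq_len(k)
    cls <- relabel[km$cluster]
    data <- data.frame(region_id = rownames(occ), class = cls,
                       stringsAsFactors = FALSE)
    list(assignment = data,
         centers = km$centers[ord, , drop = FALSE],
         withinss = km$tot.withinss,
         initss = best$initss)
}

#' Choose k by robustness of proximity enrichment
#'
#' For each candidate k, regions are clustered `R` times with different
#' seeds, and each clustering is scored by proximity enrichment of the
#' supplied differential-response gene sets around each cluster's regions
#' ([proximityEnrichmentScan()]). A clustering is *robust* when (i) every
#' cluster attains enrichment `p < threshold` for at least one gene set at
#' some distance, and (ii) every gene set is the best (minimum-p) match of
#' at least one cluster — i.e. all planted response classes are resolved.
#' k is robust when at least `r` of the `R` reseeded clusterings are, and
#' the selected k is the first robust candidate.
#'
#' @param occ region x feature matrix (rownames = region ids).
#' @param regions named `GRanges` of the regions.
#' @param deGeneSets named list of character vectors of DE gene ids, one
#'   per response class.
#' @param genes gene annotation data.frame (`gene_id`, `chrom`, `tss`).
#' @param ks candidate ks, ascending (default 2:8).
#' @param R clusterings per k (default 5); `r` of them must be robust
#'   (default 4).
#' @param r see `R`.
#' @param threshold enrichment p-value threshold (default 1e-3).
#' @param grid distance grid passed to the proximity scan.
#' @param seed base seed; per-run seeds are derived from it.
#' @return list with `k` (selected k or `NA` if none robust) and `report`
#'   (per k and replicate: robust flag, clusters enriched, sets covered).
#' @export
selectK <- function(occ, regions, deGeneSets, genes, ks = 2:8, R = 5L,
                    r = 4L, threshold = 1e-3,
                    grid = proximityGrid(), seed = 1L) {
    stopifnot(!is.null(names(deGeneSets)), is.data.frame(genes))
    ks <- sort(ks)
    rows <- list()
    chosen <- NA_integer_
    for (k in ks) {
        robustRuns <- 0L
        for (rep in seq_len(R)) {
            km <- kmeansClasses(occ, k,
                                seed = deriveSeed(seed, paste0("k", k, "_",
                                                               rep)))
            cls <- km$assignment
            minp <- matrix(NA_real_, k, length(deGeneSets),
                           dimnames = list(NULL, names(deGeneSets)))
            for (ci in seq_len(k)) {
                rids <- cls$region_id[cls$class == ci]
                cregs <- regions[names(regions) %in% rids]
                for (s in names(deGeneSets)) {
                    cur <- proximityEnrichmentScan(deGeneSets[[s]], genes,
                                                   cregs, grid = grid)
                    minp[ci, s] <- min(pValues(cur))
                }
            }
            enriched <- apply(minp, 1L, min) < threshold
            best <- names(deGeneSets)[apply(minp, 1L, which.min)]
            covered <- unique(best[enriched])
            ok <- all(enriched) && length(covered) == length(deGeneSets)
            robustRuns <- robustRuns + ok
            rows[[length(rows) + 1L]] <- data.frame(
                k = k, replicate = rep, robust = ok,
                n_enriched = sum(enriched),
                n_covered = length(covered))
        }
        if (is.na(chosen) && robustRuns >= r) chosen <- k
    }
    list(k = chosen, report = do.call(rbind, rows))
}
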