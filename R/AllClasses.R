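#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   rowRanges
NULL

#' Position frequency matrix for a DNA motif
#'
#' Stores a motif as an L x 4 matrix of base counts over the alphabet
#' A, C, G, T (one row per motif position), together with a pseudocount
#' used when the counts are converted to log-odds weights.
#'
#' @slot name single string, the motif name (e.g. a database identifier).
#' @slot counts numeric L x 4 matrix with column names A, C, G, T; all
#'   entries non-negative and every row sum positive.
#' @slot pseudocount single positive number added (spread by background
#'   frequency) before normalising counts to probabilities.
#'
#' @seealso [readJaspar()], [consensusPFM()], [scorePwm()]
#' @export
setClass("MotifMatrix",
    representation(name = "character", counts = "matrix",
                   pseudocount = "numeric"))

setValidity("MotifMatrix", function(object) {
    msg <- character()
    cnt <- object@counts
    if (length(object@name) != 1L || is.na(object@name))
        msg <- c(msg, "'name' must be a single string")
    if (!is.numeric(cnt) || ncol(cnt) != 4L)
        msg <- c(msg, "'counts' must be a numeric L x 4 matrix")
    else {
        if (!identical(colnames(cnt), c("A", "C", "G", "T")))
            msg <- c(msg, "'counts' columns must be named A, C, G, T")
        if (nrow(cnt) < 1L)
            msg <- c(msg, "motif length must be >= 1")
        if (any(cnt < 0))
            msg <- c(msg, "'counts' must be non-negative")
        if (any(rowSums(cnt) <= 0))
            msg <- c(msg, "every motif position must have a positive count sum")
    }
    if (length(object@pseudocount) != 1L || object@pseudocount <= 0)
        msg <- c(msg, "'pseudocount' must be a single positive number")
    if (length(msg)) msg else TRUE
})

#' Construct a MotifMatrix
#'
#' @param name motif name.
#' @param counts numeric L x 4 count matrix (rows = positions). Columns are
#'   taken in the order A, C, G, T; if column names are present they are used
#'   to reorder.
#' @param pseudocount positive pseudocount, default 0.8 (spread over the
#'   four bases proportionally to the background when scoring).
#' @return a [MotifMatrix-class] object.
#' @examples
#' m <- motifMatrix("toy", matrix(c(10, 0, 0, 0, 0, 10, 0, 0), 2, 4,
#'                  byrow = TRUE, dimnames = list(NULL, c("A","C","G","T"))))
#' motifLength(m)
#' @export
motifMatrix <- function(name, counts, pseudocount = 0.8) {
    counts <- as.matrix(counts)
    if (!is.null(colnames(counts))) {
        if (!setequal(colnames(counts), c("A", "C", "G", "T")))
            stop("motif count columns must be A, C, G, T")
        counts <- counts[, c("A", "C", "G", "T"), drop = FALSE]
    } else {
        if (ncol(counts) != 4L)
            stop("motif count matrix must have 4 columns")
        colnames(counts) <- c("A", "C", "G", "T")
    }
    storage.mode(counts) <- "double"
    new("MotifMatrix", name = as.character(name), counts = counts,
        pseudocount = pseudocount)
}

#' @describeIn motifMatrix motif length (number of positions).
#' @param x a `MotifMatrix`.
#' @export
motifLength <- function(x) nrow(x@counts)

#' @describeIn motifMatrix consensus string (most frequent base per position,
#'   ties resolved alphabetically).
#' @export
motifConsensus <- function(x) {
    paste(colnames(x@counts)[apply(x@counts, 1L, which.max)], collapse = "")
}

setMethod("show", "MotifMatrix", function(object) {
    cat(sprintf("MotifMatrix '%s': %d positions, consensus %s\n",
                object@name, motifLength(object), motifConsensus(object)))
})

#' Region-by-sample count container for TF binding or expression
#'
#' A thin extension of [SummarizedExperiment::RangedSummarizedExperiment]
#' holding a raw count matrix (assay `"counts"`) over genomic regions
#' (rows) and ChIP/RNA samples (columns), with the sample annotation the
#' downstream statistics need: `tf`, `condition`, `replicate` and
#' `lib_size` in `colData`. Library-size normalisation adds an extra assay
#' rather than overwriting the raw counts, and the normalisation state is
#' recorded in `metadata()`.
#'
#' @seealso [BindingExperiment()], [normaliseCounts()], [differentialTest()]
#' @export
setClass("BindingExperiment",
    contains = "RangedSummarizedExperiment")

setValidity("BindingExperiment", function(object) {
    msg <- character()
    if (!"counts" %in% names(assays(object)))
        return("assay 'counts' is required")
    cnt <- assay(object, "counts")
    if (any(cnt < 0) || any(!is.finite(cnt)))
        msg <- c(msg, "counts must be finite and non-negative")
    cd <- colData(object)
    need <- c("tf", "condition", "replicate", "lib_size")
    miss <- setdiff(need, colnames(cd))
    if (length(miss))
        msg <- c(msg, paste0("colData is missing column(s): ",
                             paste(miss, collapse = ", ")))
    if ("lib_size" %in% colnames(cd)) {
        ls <- cd$lib_size
        if (any(ls <= 0))
            msg <- c(msg, "library sizes must be positive")
        else if (any(colSums(cnt) > ls))
            msg <- c(msg, "library sizes must be >= assigned column sums")
    }
    if (is.null(rownames(cnt)) || anyDuplicated(rownames(cnt)))
        msg <- c(msg, "regions must carry unique ids (rownames)")
    if (length(msg)) msg else TRUE
})

#' Build a BindingExperiment
#'
#' @param counts integer-like region x sample matrix with unique rownames
#'   (region ids) and colnames (sample ids).
#' @param regions `GRanges` of the regions, named by region id and parallel
#'   to the rows of `counts`.
#' @param sampleInfo data.frame with one row per sample and columns `tf`,
#'   `condition`, `replicate`.
#' @param libSizes per-sample library sizes; defaults to the column sums.
#' @return a [BindingExperiment-class].
#' @examples
#' cnt <- matrix(rpois(12, 20), 3, 4,
#'               dimnames = list(paste0("r", 1:3), paste0("s", 1:4)))
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 501, 1001),
#'                              width = 200), id = paste0("r", 1:3))
#' names(gr) <- paste0("r", 1:3)
#' si <- data.frame(tf = "Oct4", condition = rep(c("pp", "dEN"), each = 2),
#'                  replicate = c(1, 2, 1, 2))
#' be <- BindingExperiment(cnt, gr, si)
#' librarySizes(be)
#' @export
BindingExperiment <- function(counts, regions, sampleInfo, libSizes = NULL) {
    counts <- as.matrix(counts)
    if (is.null(libSizes))
        libSizes <- colSums(counts)
    stopifnot(length(regions) == nrow(counts),
              nrow(sampleInfo) == ncol(counts))
    if (is.null(names(regions)))
        names(regions) <- rownames(counts)
    cd <- DataFrame(sampleInfo)
    cd$lib_size <- as.numeric(libSizes)
    rownames(cd) <- colnames(counts)
    se <- SummarizedExperiment(assays = list(counts = counts),
                               rowRanges = regions, colData = cd)
    metadata(se)$normalised <- FALSE
    metadata(se)$scale <- NA_character_
    new("BindingExperiment", se)
}

#' @describeIn BindingExperiment per-sample library sizes.
#' @param object a `BindingExperiment`.
#' @export
setGeneric("librarySizes", function(object) standardGeneric("librarySizes"))

#' @rdname BindingExperiment
#' @export
setMethod("librarySizes", "BindingExperiment",
          function(object) structure(colData(object)$lib_size,
                                     names = colnames(object)))

#' @describeIn BindingExperiment has a normalised assay been computed?
#' @export
setGeneric("isNormalised", function(object) standardGeneric("isNormalised"))

#' @rdname BindingExperiment
#' @export
setMethod("isNormalised", "BindingExperiment",
          function(object) isTRUE(metadata(object)$normalised))

setMethod("show", "BindingExperiment", function(object) {
    callNextMethod()
    cat(sprintf("normalised: %s%s\n", isNormalised(object),
                if (isNormalised(object))
                    paste0(" (", metadata(object)$scale, ")") else ""))
})

#' Distance-indexed enrichment curve
#'
#' Result container for the two enrichment statistics: observed and
#' expected counts over an ordered grid of distances, with right-tail
#' p-values (Poisson for motif-pair spacing, hypergeometric for gene
#' proximity) and their -log10 transform. `meta` records how the curve was
#' produced (test type, shuffles, seed, grid/bin definition, underflow
#' clamp).
#'
#' @slot grid ordered numeric distances in bp (bin midpoints for binned
#'   curves, scan radii for proximity curves).
#' @slot observed observed counts per grid point.
#' @slot expected expected counts per grid point under the null.
#' @slot pvalue right-tail p-values in \[0, 1\].
#' @slot neglog10p -log10(pvalue), computed after clamping underflowed
#'   p-values at the clamp recorded in `meta$clamp`.
#' @slot meta named list of provenance fields.
#'
#' @seealso [poissonEnrichment()], [proximityEnrichmentScan()]
#' @export
setClass("EnrichmentCurve",
    representation(grid = "numeric", observed = "numeric",
                   expected = "numeric", pvalue = "numeric",
                   neglog10p = "numeric", meta = "list"))

setValidity("EnrichmentCurve", function(object) {
    n <- length(object@grid)
    msg <- character()
    if (length(object@observed) != n || length(object@expected) != n ||
        length(object@pvalue) != n || length(object@neglog10p) != n)
        msg <- c(msg, "all curve components must have equal length")
    if (is.unsorted(object@grid, strictly = FALSE))
        msg <- c(msg, "'grid' must be ordered")
    if (any(object@pvalue < 0 | object@pvalue > 1, na.rm = TRUE))
        msg <- c(msg, "p-values must lie in [0, 1]")
    if (any(object@observed < 0, na.rm = TRUE) ||
        any(object@expected < 0, na.rm = TRUE))
        msg <- c(msg, "observed/expected must be non-negative")
    if (length(msg)) msg else TRUE
})

#' @describeIn EnrichmentCurve distance grid accessor.
#' @param x an `EnrichmentCurve`.
#' @export
distanceGrid <- function(x) x@grid

#' @describeIn EnrichmentCurve p-value accessor.
#' @export
pValues <- function(x) x@pvalue

#' @describeIn EnrichmentCurve observed-count accessor.
#' @export
observedCounts <- function(x) x@observed

#' @describeIn EnrichmentCurve expected-count accessor.
#' @export
expectedCounts <- function(x) x@expected

#' @describeIn EnrichmentCurve curve metadata accessor.
#' @export
curveMeta <- function(x) x@meta

#' @export
#' @method as.data.frame EnrichmentCurve
as.data.frame.EnrichmentCurve <- function(x, ...) {
    data.frame(distance = x@grid, observed = x@observed,
               expected = x@expected, pvalue = x@pvalue,
               neglog10p = x@neglog10p)
}

setMethod("show", "EnrichmentCurve", function(object) {
    i <- which.min(object@pvalue)
    cat(sprintf(
        "EnrichmentCurve (%s): %d distances in [%g, %g] bp\n",
        if (is.null(object@meta$test)) "?" else object@meta$test,
        length(object@grid), min(object@grid), max(object@grid)))
    if (length(i))
        cat(sprintf("  min p = %.3g at %g bp (obs %g, exp %.3g)\n",
                    object@pvalue[i], object@grid[i], object@observed[i],
                    object@expected[i]))
})

#' Gaussian-process trend fit
#'
#' Exact GP regression fit (squared-exponential kernel plus independent
#' noise) of a response against an ordered predictor, as used to display
#' the trend of binding fold change against motif-variant composition.
#' Stores the training data, the posterior mean and standard deviation of
#' the latent function on a prediction grid, the (possibly optimised)
#' kernel hyperparameters, and numerical details (jitter added for
#' conditioning, log marginal likelihood).
#'
#' @slot x,y training inputs and responses.
#' @slot predX prediction grid.
#' @slot postMean,postSd posterior mean and sd of the latent function on
#'   `predX`.
#' @slot kernelParams named numeric: `lengthscale`, `sigf2` (signal
#'   variance), `sign2` (noise variance).
#' @slot logML log marginal likelihood at the returned hyperparameters.
#' @slot jitter diagonal jitter that had to be added (0 when none).
#' @slot meta list: optimiser settings, seed, centring constant.
#' @seealso [gpTrend()]
#' @export
setClass("TrendFit",
    representation(x = "numeric", y = "numeric", predX = "numeric",
                   postMean = "numeric", postSd = "numeric",
                   kernelParams = "numeric", logML = "numeric",
                   jitter = "numeric", meta = "list"))

setValidity("TrendFit", function(object) {
    msg <- character()
    if (length(object@x) != length(object@y))
        msg <- c(msg, "'x' and 'y' must be parallel")
    if (length(object@predX) != length(object@postMean) ||
        length(object@predX) != length(object@postSd))
        msg <- c(msg, "prediction grid and posterior arrays must be parallel")
    if (any(object@postSd < 0, na.rm = TRUE))
        msg <- c(msg, "posterior sd must be non-negative")
    if (length(msg)) msg else TRUE
})

#' @export
#' @method as.data.frame TrendFit
as.data.frame.TrendFit <- function(x, ...) {
    data.frame(x = x@predX, mean = x@postMean, sd = x@postSd)
}

#' @describeIn TrendFit kernel hyperparameters (lengthscale, signal and
#'   noise variances).
#' @param x a `TrendFit`.
#' @export
kernelParams <- function(x) x@kernelParams

setMethod("show", "TrendFit", function(object) {
    p <- object@kernelParams
    cat(sprintf(paste0(
        "TrendFit: %d training points, %d-point grid\n",
        "  lengthscale %.4g, signal var %.4g, noise var %.4g, logML %.4g\n"),
        length(object@x), length(object@predX),
        p[["lengthscale"]], p[["sigf2"]], p[["sign2"]], object@logML))
})
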