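# Motif machinery for the extended nuclear-receptor half-site
# TCAAGG(T/C)CA: consensus scanning with 0/1 mismatches, trimmed-consensus
# scanning with a free seventh base, PWM log-odds scoring, region variant
# classes and the seventh-base frequency profile along ranked regions.

#' Half-site consensus variants
#'
#' The 9-bp extended half-site bound by Esrrb (`T` variant) and Nr5a2
#' (`C` variant); the trimmed form leaves the discriminating seventh base
#' free.
#' @name halfsite
#' @return a character scalar.
#' @export
halfsiteT <- function() "TCAAGGTCA"

#' @rdname halfsite
#' @export
halfsiteC <- function() "TCAAGGCCA"

#' @rdname halfsite
#' @export
halfsiteTrimmed <- function() "TCAAGGNCA"

emptyHits <- function() {
    data.frame(region_id = character(), offset = integer(),
               strand = character(), mismatches = integer(),
               score = numeric(), seventh_base = character(),
               motif_name = character(), width = integer(),
               stringsAsFactors = FALSE)
}

# Hamming scan of one encoded sequence on the + orientation only.
# Returns 1-based window starts and mismatch counts for windows with
# mismatches <= maxMismatch; positions in `freePos` are excluded from the
# count. Sequence N (code 5) counts as a mismatch at constrained positions.
scanCodeOne <- function(code, consCode, maxMismatch, freePos = integer()) {
    L <- length(consCode)
    n <- length(code) - L + 1L
    if (n < 1L)
        return(list(pos = integer(), mism = integer()))
    mism <- integer(n)
    for (j in seq_len(L)) {
        if (j %in% freePos) next
        seg <- code[j:(j + n - 1L)]
        mism <- mism + ((seg != consCode[j]) | (seg == 5L))
    }
    keep <- which(mism <= maxMismatch)
    list(pos = keep, mism = mism[keep])
}

# Seventh base (in motif orientation) for hits at 0-based offsets.
seventhBaseOf <- function(code, offset0, strand, L) {
    if (L < 7L) return(rep(NA_character_, length(offset0)))
    idx <- ifelse(strand == "+", offset0 + 7L, offset0 + L - 6L)
    b <- code[idx]
    b <- ifelse(strand == "+", b, c(4L, 3L, 2L, 1L, 5L)[b])
    out <- rep("other", length(b))
    out[b == 4L] <- "T"
    out[b == 2L] <- "C"
    out
}

scanSeqConsensus <- function(seq, regionId, consCode, maxMismatch,
                             bothStrands, motifName, freePos = integer()) {
    code <- encodeDNA(seq)
    L <- length(consCode)
    len <- length(code)
    fw <- scanCodeOne(code, consCode, maxMismatch, freePos)
    off <- fw$pos - 1L
    strand <- rep("+", length(off))
    mism <- fw$mism
    if (bothStrands) {
        rc <- revCompCode(code)
        rv <- scanCodeOne(rc, consCode, maxMismatch, freePos)
        if (length(rv$pos)) {
            off <- c(off, len - (rv$pos - 1L) - L)
            strand <- c(strand, rep("-", length(rv$pos)))
            mism <- c(mism, rv$mism)
        }
    }
    if (!length(off)) return(emptyHits())
    sb <- seventhBaseOf(code, off, strand, L)
    h <- data.frame(region_id = regionId, offset = as.integer(off),
                    strand = strand, mismatches = as.integer(mism),
                    score = NA_real_, seventh_base = sb,
                    motif_name = motifName, width = L,
                    stringsAsFactors = FALSE)
    h[order(h$offset, h$strand), , drop = FALSE]
}

asSeqList <- function(seqs) {
    if (methods::is(seqs, "XStringSet")) {
        out <- as.character(seqs)
    } else if (is.character(seqs)) {
        out <- seqs
    } else stop("'seqs' must be a DNAStringSet or character vector")
    if (is.null(names(out)))
        names(out) <- if (length(out) == 1L) "seq" else
            paste0("seq", seq_along(out))
    out
}

#' Scan sequences for a consensus motif with at most `maxMismatch` mismatches
#'
#' Reports every window, on one or both strands, whose Hamming distance to
#' the consensus is at most `maxMismatch`. `N` bases never match a
#' constrained consensus position. Hit offsets are 0-based positions of
#' the leftmost matched base on the + strand of the scanned sequence,
#' whatever the hit strand; `seventh_base` is the base actually read at
#' motif position 7 in motif orientation (`NA` for motifs shorter than 7).
#'
#' @param seqs named character vector or `DNAStringSet` of region
#'   sequences; names become `region_id`.
#' @param consensus consensus string over A, C, G, T.
#' @param maxMismatch maximum Hamming distance, normally 0 or 1.
#' @param bothStrands scan the reverse complement too (default `TRUE`).
#' @param motifName label stored in the `motif_name` column.
#' @return a data.frame of hits with columns `region_id`, `offset`,
#'   `strand`, `mismatches`, `score` (NA here), `seventh_base`,
#'   `motif_name`, `width`, sorted by offset within each region.
#' @examples
#' scanConsensus(c(r1 = "TTTCAAGGTCATT"), "TCAAGGTCA", maxMismatch = 0)
#' @export
scanConsensus <- function(seqs, consensus, maxMismatch = 1L,
                          bothStrands = TRUE, motifName = consensus) {
    stopIfNot1String(consensus, "consensus")
    if (maxMismatch < 0 || maxMismatch != floor(maxMismatch))
        stop("'maxMismatch' must be a non-negative integer")
    consCode <- encodeDNA(consensus)
    if (any(consCode == 5L))
        stop("consensus must be over A, C, G, T (use scanTrimmedHalfsite ",
             "for a free seventh base)")
    ss <- asSeqList(seqs)
    res <- lapply(names(ss), function(id)
        scanSeqConsensus(ss[[id]], id, consCode, maxMismatch, bothStrands,
                         motifName))
    do.call(rbind, c(res, list(emptyHits())))
}

#' Scan for the trimmed half-site TCAAGG?CA with a free seventh base
#'
#' Matches the extended half-site consensus with complete freedom at the
#' seventh position: that base is excluded from the mismatch count and is
#' reported literally in `seventh_base` (`T`, `C` or `other`).
#'
#' @inheritParams scanConsensus
#' @return hit data.frame as for [scanConsensus()], `motif_name`
#'   `"TCAAGGNCA"`.
#' @examples
#' scanTrimmedHalfsite(c(r1 = "TCAAGGGCA"), maxMismatch = 0)$seventh_base
#' @export
scanTrimmedHalfsite <- function(seqs, maxMismatch = 1L, bothStrands = TRUE) {
    if (maxMismatch < 0 || maxMismatch != floor(maxMismatch))
        stop("'maxMismatch' must be a non-negative integer")
    consCode <- encodeDNA(halfsiteT())
    ss <- asSeqList(seqs)
    res <- lapply(names(ss), function(id)
        scanSeqConsensus(ss[[id]], id, consCode, maxMismatch, bothStrands,
                         halfsiteTrimmed(), freePos = 7L))
    do.call(rbind, c(res, list(emptyHits())))
}

# Log-odds weight matrix (rows: codes A,C,G,T,N; N scores the worst base)
pwmWeights <- function(motif, background) {
    cnt <- motif@counts
    bg <- background / sum(background)
    if (any(bg <= 0)) stop("background frequencies must be positive")
    prob <- (cnt + motif@pseudocount * matrix(bg, nrow(cnt), 4L,
                                              byrow = TRUE)) /
        (rowSums(cnt) + motif@pseudocount)
    W <- log2(sweep(prob, 2L, bg, "/"))
    cbind(W, N = apply(W, 1L, min))
}

scoreCodeOne <- function(code, W) {
    L <- nrow(W)
    n <- length(code) - L + 1L
    if (n < 1L) return(numeric())
    sc <- numeric(n)
    for (j in seq_len(L))
        sc <- sc + W[j, ][code[j:(j + n - 1L)]]
    sc
}

#' Score every window of each sequence against a PWM
#'
#' Computes the summed log2 odds score
#' `sum_j log2(p_j(base) / bg(base))` for every window on both strands,
#' where `p_j` are the pseudocount-adjusted position probabilities of the
#' motif. No threshold is applied; thresholding (e.g. the above-median
#' filter used for motif-pair analysis) is a separate step. `N` bases
#' contribute the least favourable score of their position.
#'
#' @param seqs named character vector or `DNAStringSet`.
#' @param motif a [MotifMatrix-class].
#' @param background base frequencies in A, C, G, T order (normalised
#'   internally); all must be positive.
#' @return hit data.frame as for [scanConsensus()] with `score` filled and
#'   `mismatches` `NA`.
#' @examples
#' m <- consensusPFM("ACGT")
#' scorePwm(c(r1 = "ACGTACGT"), m)
#' @export
scorePwm <- function(seqs, motif, background = c(0.25, 0.25, 0.25, 0.25)) {
    stopifnot(methods::is(motif, "MotifMatrix"))
    if (length(background) != 4L)
        stop("'background' must have 4 frequencies (A, C, G, T)")
    if (any(background <= 0))
        stop("background frequencies must be positive")
    W <- pwmWeights(motif, background)
    L <- nrow(motif@counts)
    ss <- asSeqList(seqs)
    res <- lapply(names(ss), function(id) {
        code <- encodeDNA(ss[[id]])
        len <- length(code)
        fw <- scoreCodeOne(code, W)
        rv <- scoreCodeOne(revCompCode(code), W)
        off <- c(seq_along(fw) - 1L, if (length(rv))
            len - (seq_along(rv) - 1L) - L)
        strand <- c(rep("+", length(fw)), rep("-", length(rv)))
        if (!length(off)) return(emptyHits())
        sb <- seventhBaseOf(code, off, strand, L)
        h <- data.frame(region_id = id, offset = as.integer(off),
                        strand = strand, mismatches = NA_integer_,
                        score = c(fw, rv), seventh_base = sb,
                        motif_name = motif@name, width = L,
                        stringsAsFactors = FALSE)
        h[order(h$offset, h$strand), , drop = FALSE]
    })
    do.call(rbind, c(res, list(emptyHits())))
}

#' Classify regions by the seventh-base variant content of their half-sites
#'
#' Assigns each region to one of `T_only`, `C_only`, `both` or `none`
#' according to the seventh-base labels of its trimmed-half-site hits: the
#' discriminating base itself is read literally (a hit whose seventh base
#' is neither T nor C counts towards neither variant), while up to
#' `maxMismatch` mismatches are tolerated in the rest of the consensus.
#'
#' @param hits hit data.frame from [scanTrimmedHalfsite()].
#' @param regionIds character vector of all region ids to classify
#'   (regions without hits become `"none"`).
#' @param maxMismatch mismatch tolerance applied to the hits (default 1).
#' @return named factor over `regionIds` with levels `T_only`, `C_only`,
#'   `both`, `none`.
#' @export
classifyRegionsByVariant <- function(hits, regionIds, maxMismatch = 1L) {
    if (anyDuplicated(regionIds)) stop("'regionIds' must be unique")
    extra <- setdiff(unique(hits$region_id), regionIds)
    if (length(extra))
        stop("consistency error: hits reference region(s) absent from ",
             "'regionIds': ", paste(utils::head(extra, 3L), collapse = ", "))
    h <- hits[hits$mismatches <= maxMismatch, , drop = FALSE]
    hasT <- regionIds %in% h$region_id[h$seventh_base == "T"]
    hasC <- regionIds %in% h$region_id[h$seventh_base == "C"]
    cls <- ifelse(hasT & hasC, "both",
                  ifelse(hasT, "T_only", ifelse(hasC, "C_only", "none")))
    factor(stats::setNames(cls, regionIds),
           levels = c("T_only", "C_only", "both", "none"))
}

#' Log-ratio of binding between two factors
#'
#' `log2((a + pseudo) / (b + pseudo))` on library-normalised binding
#' values (e.g. RPM); the pseudo-value guards against empty regions.
#'
#' @param a,b numeric vectors of normalised binding per region.
#' @param pseudo pseudo-value added to both, default 0.5.
#' @return numeric vector of log2 ratios.
#' @export
bindingRatio <- function(a, b, pseudo = 0.5) {
    stopifnot(length(a) == length(b), pseudo > 0)
    log2((a + pseudo) / (b + pseudo))
}

#' Seventh-base variant frequencies along ranked regions
#'
#' Given regions ordered by a binding statistic (conventionally decreasing
#' Esrrb/Nr5a2 binding ratio) and trimmed-half-site hits, computes the
#' frequency of T- and C-seventh-base hits among all hits inside a window
#' of consecutive ranked regions, either sliding (step 1) or tiled
#' (non-overlapping).
#'
#' @param rankedRegionIds region ids in rank order.
#' @param hits hits from [scanTrimmedHalfsite()] (hits in regions outside
#'   the ranking raise an error).
#' @param window window size in regions (>= 1, <= number of regions).
#' @param mode `"sliding"` (default) or `"tiled"`.
#' @return data.frame with `window`, `start_rank`, `center_rank`,
#'   `n_hits`, `freq_T`, `freq_C` (frequencies `NA` in hit-free windows;
#'   `freq_T + freq_C <= 1`, remainder "other").
#' @export
seventhBaseProfile <- function(rankedRegionIds, hits, window = 100L,
                               mode = c("sliding", "tiled")) {
    mode <- match.arg(mode)
    n <- length(rankedRegionIds)
    if (anyDuplicated(rankedRegionIds)) stop("ranked region ids not unique")
    if (window < 1L || window > n)
        stop("'window' must be between 1 and the number of ranked regions")
    extra <- setdiff(unique(hits$region_id), rankedRegionIds)
    if (length(extra))
        stop("consistency error: hits reference unranked region(s): ",
             paste(utils::head(extra, 3L), collapse = ", "))
    idx <- match(hits$region_id, rankedRegionIds)
    nT <- tabulate(idx[hits$seventh_base == "T"], nbins = n)
    nC <- tabulate(idx[hits$seventh_base == "C"], nbins = n)
    nA <- tabulate(idx, nbins = n)
    starts <- if (mode == "sliding") seq_len(n - window + 1L)
              else seq(1L, n - window + 1L, by = window)
    csT <- c(0, cumsum(nT)); csC <- c(0, cumsum(nC)); csA <- c(0, cumsum(nA))
    tot <- csA[starts + window] - csA[starts]
    wT <- csT[starts + window] - csT[starts]
    wC <- csC[starts + window] - csC[starts]
    data.frame(window = seq_along(starts), start_rank = starts,
               center_rank = starts + (window - 1) / 2,
               n_hits = tot,
               freq_T = ifelse(tot > 0, wT / tot, NA_real_),
               freq_C = ifelse(tot > 0, wC / tot, NA_real_))
}
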