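# Independent oracles and small fixtures used across the test files.
# All oracles are deliberately naive (string loops, full enumeration) and
# never share code with the implementation they check.

rcOracle <- function(s) {
    chartr("ACGTN", "TGCAN",
           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

randomSeq <- function(n, letters = c("A", "C", "G", "T")) {
    paste(sample(letters, n, replace = TRUE), collapse = "")
}

# Brute-force Hamming scan: every window on both strands via substring
# comparison. freePos positions are skipped in the mismatch count.
# Returns offsets (0-based, leftmost base on the + strand), strand and
# mismatch counts, sorted like the implementation output.
bruteScan <- function(seq, consensus, maxMismatch, freePos = integer()) {
    L <- nchar(consensus)
    cons <- strsplit(consensus, "")[[1]]
    countMm <- function(win) {
        w <- strsplit(win, "")[[1]]
        sum(vapply(seq_len(L), function(j) {
            if (j %in% freePos) return(FALSE)
            w[j] != cons[j] || w[j] == "N"
        }, TRUE))
    }
    out <- list()
    n <- nchar(seq) - L + 1
    if (n >= 1) for (i in seq_len(n)) {
        win <- substr(seq, i, i + L - 1)
        mm <- countMm(win)
        if (mm <= maxMismatch)
            out[[length(out) + 1]] <- data.frame(offset = i - 1,
                                                 strand = "+",
                                                 mismatches = mm)
        mmR <- countMm(rcOracle(win))
        if (mmR <= maxMismatch)
            out[[length(out) + 1]] <- data.frame(offset = i - 1,
                                                 strand = "-",
                                                 mismatches = mmR)
    }
    if (!length(out))
        return(data.frame(offset = integer(), strand = character(),
                          mismatches = integer()))
    d <- do.call(rbind, out)
    d[order(d$offset, d$strand), , drop = FALSE]
}

# Exhaustive hypergeometric right tail by enumerating every n-subset of a
# universe with K successes.
bruteHyperTail <- function(N, K, n, k) {
    if (n == 0) return(as.numeric(k <= 0))
    subsets <- utils::combn(N, n)
    hits <- colSums(subsets <= K)  # items 1..K are the successes
    mean(hits >= k)
}

# Poisson upper tail P(X >= k) summed in log space (handles p << 1e-300).
# Returns the log of the tail probability.
brutePoisLogTail <- function(k, lambda, extra = 2000L) {
    if (k <= 0) return(0)
    i <- k:(k + extra)
    lt <- stats::dpois(i, lambda, log = TRUE)
    m <- max(lt)
    m + log(sum(exp(lt - m)))
}

# cached synthetic studies so acceptance tests can share one generation
.studyCache <- new.env(parent = emptyenv())
getStudy <- function(preset, seed) {
    key <- paste(preset, seed, sep = "_")
    if (is.null(.studyCache[[key]]))
        .studyCache[[key]] <- syntheticStudy(preset, seed = seed)
    .studyCache[[key]]
}

getFullScan <- function(seed) {
    key <- paste("scan", seed, sep = "_")
    if (is.null(.studyCache[[key]])) {
        st <- getStudy("full", seed)
        seqs <- regionSequences(st$genome, st$regions)
        .studyCache[[key]] <- list(
            hs = scanTrimmedHalfsite(seqs, maxMismatch = 1),
            os = scanConsensus(seqs, octSoxConsensus(), maxMismatch = 2,
                               motifName = "OctSox"))
    }
    .studyCache[[key]]
}

rpmMatrix <- function(be) {
    sweep(SummarizedExperiment::assay(be, "counts"), 2,
          librarySizes(be), "/") * 1e6
}
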