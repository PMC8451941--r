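test_that("consensus scanning: identity, Hamming boundary, N handling", {
    h <- scanConsensus(c(r1 = "TCAAGGTCA"), "TCAAGGTCA", maxMismatch = 0)
    expect_equal(nrow(h), 1L)
    expect_equal(h$offset, 0L)
    expect_identical(h$strand, "+")
    expect_identical(h$seventh_base, "T")
    expect_equal(h$mismatches, 0L)

    expect_equal(nrow(scanConsensus(c(r1 = "TCAAGGACA"), "TCAAGGTCA",
                                    maxMismatch = 0)), 0L)
    h1 <- scanConsensus(c(r1 = "TCAAGGACA"), "TCAAGGTCA", maxMismatch = 1)
    expect_equal(h1$mismatches, 1L)

    # N never matches a constrained position
    expect_equal(nrow(scanConsensus(c(r1 = "TCAAGGNCA"), "TCAAGGTCA",
                                    maxMismatch = 0)), 0L)
    # consensus shorter than sequence is fine; longer gives empty result
    expect_equal(nrow(scanConsensus(c(r1 = "ACGT"), "TCAAGGTCA", 1)), 0L)
    expect_error(scanConsensus(c(r1 = "ACGT"), "", 0))
})

test_that("minus-strand hits report leftmost + strand offsets and the
           motif-orientation seventh base", {
    # RC of TCAAGGCCA is TGGCCTTGA
    h <- scanConsensus(c(r1 = "AATGGCCTTGACC"), "TCAAGGCCA", 0)
    expect_identical(h$strand, "-")
    expect_equal(h$offset, 2L)
    expect_identical(h$seventh_base, "C")
})

test_that("scan results equal the brute-force Hamming oracle", {
    set.seed(42)
    for (i in 1:25) {
        s <- randomSeq(sample(60:400, 1),
                       letters = c("A", "C", "G", "T", "N"))
        for (mm in 0:1) {
            got <- scanConsensus(c(r = s), "TCAAGGTCA", mm)
            exp <- bruteScan(s, "TCAAGGTCA", mm)
            expect_equal(got$offset, exp$offset)
            expect_equal(got$strand, exp$strand)
            expect_equal(got$mismatches, exp$mismatches)
        }
    }
})

test_that("scanning is invariant under reverse complementation", {
    set.seed(7)
    for (i in 1:10) {
        s <- randomSeq(300)
        h <- scanConsensus(c(r = s), "TCAAGGTCA", 0)
        hr <- scanConsensus(c(r = rcOracle(s)), "TCAAGGTCA", 0)
        # coordinates map through offset' = len - offset - L, strands flip
        expect_setequal(nchar(s) - h$offset - 9L, hr$offset)
        expect_equal(nrow(h), nrow(hr))
    }
})

test_that("exact consensus scan agrees with Biostrings matchPattern", {
    set.seed(11)
    s <- randomSeq(5000)
    got <- scanConsensus(c(r = s), "TCAAGG", 0, bothStrands = FALSE)
    ref <- Biostrings::matchPattern("TCAAGG", Biostrings::DNAString(s))
    expect_equal(got$offset, BiocGenerics::start(ref) - 1L)
})

test_that("trimmed half-site scan leaves the seventh base free", {
    h <- scanTrimmedHalfsite(c(r1 = "TCAAGGGCA"), 0)
    expect_equal(nrow(h), 1L)
    expect_identical(h$seventh_base, "other")
    expect_identical(scanTrimmedHalfsite(c(r1 = "TCAAGGTCA"),
                                         0)$seventh_base, "T")
    expect_identical(scanTrimmedHalfsite(c(r1 = "TCAAGGCCA"),
                                         0)$seventh_base, "C")
    # oracle equivalence with the free position masked
    set.seed(13)
    for (i in 1:10) {
        s <- randomSeq(sample(100:2000, 1))
        got <- scanTrimmedHalfsite(c(r = s), 1)
        exp <- bruteScan(s, "TCAAGGTCA", 1, freePos = 7)
        expect_equal(got$offset, exp$offset)
        expect_equal(got$strand, exp$strand)
        expect_equal(got$mismatches, exp$mismatches)
    }
})

test_that("trimmed hits contain the union of both exact variant scans", {
    set.seed(17)
    s <- randomSeq(20000)
    tr <- scanTrimmedHalfsite(c(r = s), 0)
    keyT <- with(scanConsensus(c(r = s), halfsiteT(), 0),
                 paste(offset, strand))
    keyC <- with(scanConsensus(c(r = s), halfsiteC(), 0),
                 paste(offset, strand))
    expect_true(all(c(keyT, keyC) %in% with(tr, paste(offset, strand))))
})

test_that("seventh_base always equals the base read in motif orientation", {
    set.seed(23)
    s <- randomSeq(50000)
    h <- scanTrimmedHalfsite(c(r = s), 1)
    expect_gt(nrow(h), 0)
    for (i in seq_len(nrow(h))) {
        win <- substr(s, h$offset[i] + 1, h$offset[i] + 9)
        if (h$strand[i] == "-") win <- rcOracle(win)
        b <- substr(win, 7, 7)
        expect_identical(h$seventh_base[i],
                         if (b %in% c("T", "C")) b else "other")
    }
})

test_that("PWM scoring matches the closed form on an indicator matrix", {
    m <- consensusPFM("ACGT", hit = 100, pseudocount = 0.8)
    h <- scorePwm(c(r = "ACGTACGT"), m)
    # per matching position: log2(((100 + .2)/100.8) / 0.25)
    perfect <- 4 * log2((100.2 / 100.8) / 0.25)
    best <- h[h$offset == 0 & h$strand == "+", ]
    expect_equal(best$score, perfect, tolerance = 1e-12)
    expect_equal(max(h$score), perfect, tolerance = 1e-12)
})

test_that("PWM scores are strand-symmetric and match a per-position oracle", {
    set.seed(29)
    s <- randomSeq(1000)
    counts <- matrix(stats::runif(5 * 4, 1, 20), 5, 4,
                     dimnames = list(NULL, c("A", "C", "G", "T")))
    m <- motifMatrix("rand", counts, pseudocount = 1)
    h <- scorePwm(c(r = s), m)
    # oracle: direct per-position sum on each + window
    bg <- rep(0.25, 4)
    prob <- (counts + 1 * 0.25) / (rowSums(counts) + 1)
    W <- log2(prob / 0.25)
    colnames(W) <- c("A", "C", "G", "T")
    plus <- h[h$strand == "+", ]
    for (i in sample(nrow(plus), 50)) {
        win <- strsplit(substr(s, plus$offset[i] + 1,
                               plus$offset[i] + 5), "")[[1]]
        expect_equal(plus$score[i],
                     sum(W[cbind(1:5, match(win, colnames(W)))]),
                     tolerance = 1e-10)
    }
    # a - strand window scores like its reverse complement on +
    minus <- h[h$strand == "-", ]
    for (i in sample(nrow(minus), 20)) {
        win <- rcOracle(substr(s, minus$offset[i] + 1, minus$offset[i] + 5))
        w <- strsplit(win, "")[[1]]
        expect_equal(minus$score[i],
                     sum(W[cbind(1:5, match(w, colnames(W)))]),
                     tolerance = 1e-10)
    }
})

test_that("region variant classes follow seventh-base content", {
    seqs <- c(tOnly = "AATCAAGGTCAAA", cOnly = "AATCAAGGCCAAA",
              both = paste0("TCAAGGTCA", "GGG", "TCAAGGCCA"),
              none = randomSeq(30), otherOnly = "AATCAAGGGCAAA")
    set.seed(31)
    hits <- scanTrimmedHalfsite(seqs, 1)
    cls <- classifyRegionsByVariant(hits, names(seqs))
    expect_identical(as.character(cls[c("tOnly", "cOnly", "both")]),
                     c("T_only", "C_only", "both"))
    expect_identical(as.character(cls[["none"]]), "none")
    # a hit with an "other" seventh base supports neither variant
    expect_identical(as.character(cls[["otherOnly"]]), "none")
    expect_error(classifyRegionsByVariant(hits, c("tOnly")),
                 "consistency")
})

test_that("seventh-base profiles: degenerate windows and window = 1", {
    ids <- paste0("r", 1:6)
    hits <- data.frame(region_id = rep(ids[1:4], each = 2),
                       offset = 0L, strand = "+", mismatches = 0L,
                       score = NA_real_,
                       seventh_base = c("T", "T", "T", "C", "C", "C",
                                        "other", "T"),
                       motif_name = "TCAAGGNCA", width = 9L)
    p1 <- seventhBaseProfile(ids, hits, window = 1)
    expect_equal(p1$freq_T, c(1, 0.5, 0, 0.5, NA, NA))
    expect_equal(p1$freq_C, c(0, 0.5, 1, 0, NA, NA))
    expect_true(all(p1$freq_T + p1$freq_C <= 1, na.rm = TRUE))
    # all-T hits give freq_T 1 everywhere
    hT <- hits; hT$seventh_base <- "T"
    pT <- seventhBaseProfile(ids, hT, window = 2)
    expect_true(all(pT$freq_T[!is.na(pT$freq_T)] == 1))
    expect_error(seventhBaseProfile(ids, hits, window = 7), "window")
})
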