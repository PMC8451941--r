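mkHits <- function(region, offset, width = 9L, strand = "+",
                   motif = "m", score = NA_real_) {
    n <- length(offset)
    data.frame(region_id = rep_len(region, n), offset = offset,
               strand = rep_len(strand, n), mismatches = rep_len(0L, n),
               score = rep_len(score, n),
               seventh_base = rep_len("T", n),
               motif_name = rep_len(motif, n),
               width = rep_len(width, n), stringsAsFactors = FALSE)
}

test_that("the above-median filter is strict and per motif", {
    h <- mkHits("r1", c(0, 20, 40), score = c(1, 2, 3))
    out <- filterAboveMedian(h)
    expect_equal(out$score, 3)
    # all-equal scores leave nothing
    expect_equal(nrow(filterAboveMedian(mkHits("r1", c(0, 20),
                                               score = c(2, 2)))), 0L)
    expect_equal(nrow(filterAboveMedian(h[0, ])), 0L)
    # medians are computed within each motif's hit set
    set.seed(4)
    h2 <- rbind(mkHits("r1", seq(0, 90, 10), motif = "a",
                       score = stats::rnorm(10)),
                mkHits("r1", seq(0, 90, 10), motif = "b",
                       score = stats::rnorm(10) + 50))
    out2 <- filterAboveMedian(h2)
    for (m in c("a", "b")) {
        sc <- h2$score[h2$motif_name == m]
        expect_setequal(out2$score[out2$motif_name == m],
                        sc[sc > stats::median(sc)])
    }
})

test_that("pair distances use motif centres and never cross regions", {
    a <- mkHits("r1", 10, width = 9)    # centre 14
    b <- mkHits("r1", 60, width = 15, motif = "b")  # centre 67
    pd <- pairDistanceCounts(a, b, binWidth = 10, maxDist = 100)
    expect_equal(sum(pd$counts), 1)
    expect_equal(pd$mids[pd$counts == 1], 55)  # |14 - 67| = 53
    # cross-region pairs do not count
    b2 <- mkHits("r2", 60, width = 15, motif = "b")
    expect_equal(sum(pairDistanceCounts(a, b2, 10, 100)$counts), 0)
    # a singleton set paired with itself has only the excluded self-pair
    expect_equal(sum(pairDistanceCounts(a, a, 10, 100)$counts), 0)
    # distinct overlapping hits do count
    a2 <- rbind(a, mkHits("r1", 12, width = 9))
    expect_equal(sum(pairDistanceCounts(a2, a2, 10, 100)$counts), 2)
})

test_that("binned pair counts equal a brute-force double loop", {
    set.seed(14)
    regions <- sprintf("r%02d", 1:50)
    a <- do.call(rbind, lapply(regions, function(r)
        mkHits(r, sample(0:390, sample(0:3, 1)), width = 9)))
    b <- do.call(rbind, lapply(regions, function(r)
        mkHits(r, sample(0:380, sample(0:3, 1)), width = 15,
               motif = "b")))
    pd <- pairDistanceCounts(a, b, binWidth = 10, maxDist = 400)
    brute <- numeric(length(pd$counts))
    for (r in regions) {
        ca <- a$offset[a$region_id == r] + 4
        cb <- b$offset[b$region_id == r] + 7
        for (x in ca) for (y in cb) {
            d <- abs(x - y)
            if (d < 400) {
                bin <- floor(d / 10) + 1
                brute[bin] <- brute[bin] + 1
            }
        }
    }
    expect_equal(pd$counts, brute)
})

test_that("randomised background preserves pair totals and is seeded", {
    set.seed(15)
    regions <- sprintf("r%02d", 1:30)
    w <- stats::setNames(rep(400L, 30), regions)
    a <- do.call(rbind, lapply(regions, function(r)
        mkHits(r, sample(0:390, 2), width = 9)))
    b <- do.call(rbind, lapply(regions, function(r)
        mkHits(r, sample(0:380, 2), width = 15, motif = "b")))
    obs <- pairDistanceCounts(a, b, binWidth = 10, maxDist = 400)
    bg <- randomisedBackground(a, b, w, nShuffles = 5, seed = 3,
                               binWidth = 10, maxDist = 400)
    # shuffling preserves per-region hit counts, hence total pair count
    expect_equal(sum(bg$expected), sum(obs$counts))
    bg2 <- randomisedBackground(a, b, w, nShuffles = 5, seed = 3,
                                binWidth = 10, maxDist = 400)
    expect_identical(bg$expected, bg2$expected)
    bg3 <- randomisedBackground(a, b, w, nShuffles = 5, seed = 4,
                                binWidth = 10, maxDist = 400)
    expect_false(identical(bg$expected, bg3$expected))
    # a hit that cannot fit its region is skipped with a warning
    wShort <- stats::setNames(c(10L, w[-1]), regions)
    expect_warning(randomisedBackground(a, b, wShort, nShuffles = 1,
                                        seed = 1), "skipped")
})

test_that("Poisson right tails match closed form and handle degeneracy", {
    ec <- poissonEnrichment(10, 5)
    expect_equal(pValues(ec), exp(brutePoisLogTail(10, 5)),
                 tolerance = 1e-12)
    expect_equal(pValues(poissonEnrichment(0, 7)), 1)
    d <- poissonEnrichment(c(0, 3), c(0, 0))
    expect_equal(pValues(d), c(1, 0))
    expect_equal(curveMeta(d)$degenerate, 2L)
    # monotone in observed at fixed lambda
    p <- pValues(poissonEnrichment(0:20, rep(4, 21)))
    expect_true(all(diff(p) <= 0))
    expect_error(poissonEnrichment(-1, 2), "non-negative")
    # neglog10 clamps underflow
    big <- poissonEnrichment(5000, 1)
    expect_lte(big@neglog10p[1], 300)
})

test_that("genesWithin applies the <= x same-chromosome rule", {
    genes <- data.frame(gene_id = c("inside", "edge", "far", "otherchr"),
                        chrom = c("chr1", "chr1", "chr1", "chr2"),
                        tss = c(150L, 250L, 900L, 150L),
                        strand = "+")
    regs <- GenomicRanges::GRanges("chr1",
                                   IRanges::IRanges(101, 200))  # 0-based [100, 200)
    expect_identical(genesWithin(genes, regs, 0), "inside")
    # TSS 250 is 51 bp beyond the last region base (199, 0-based)
    expect_identical(genesWithin(genes, regs, 51),
                     c("inside", "edge"))
    expect_false("edge" %in% genesWithin(genes, regs, 50))
    expect_false("otherchr" %in% genesWithin(genes, regs, 1e6))
})

test_that("genesWithin equals a brute-force all-pairs scan", {
    set.seed(21)
    genes <- data.frame(gene_id = sprintf("g%03d", 1:200),
                        chrom = sample(c("chr1", "chr2"), 200, TRUE),
                        tss = sample(0:99999, 200), strand = "+")
    s <- sort(sample(0:95000, 50))
    regs <- GenomicRanges::GRanges(sample(c("chr1", "chr2"), 50, TRUE),
                                   IRanges::IRanges(s + 1,
                                                    s + sample(200:800,
                                                               50, TRUE)))
    for (x in c(0, 100, 5000)) {
        got <- genesWithin(genes, regs, x)
        rchr <- as.character(GenomicRanges::seqnames(regs))
        brute <- genes$gene_id[vapply(seq_len(200), function(i) {
            d <- Inf
            for (j in which(rchr == genes$chrom[i])) {
                s0 <- GenomicRanges::start(regs)[j] - 1
                e0 <- GenomicRanges::end(regs)[j]
                t <- genes$tss[i]
                d <- min(d, if (t >= s0 && t < e0) 0
                         else min(abs(s0 - t), abs(t - (e0 - 1))))
            }
            d <= x
        }, TRUE)]
        expect_setequal(got, brute)
    }
})

test_that("hypergeometric proximity scan: worked example, saturation and
           monotone construction", {
    # universe of 10 genes on a tiny chromosome; 5 within reach at x=10
    genes <- data.frame(gene_id = paste0("g", 1:10), chrom = "chr1",
                        tss = c(100:104, 5001:5005), strand = "+")
    regs <- GenomicRanges::GRanges("chr1", IRanges::IRanges(91, 110))
    de <- paste0("g", 1:4)
    cur <- proximityEnrichmentScan(de, genes, regs, grid = c(10, 1e6))
    # N=10, K=5, n=4, k=4 -> C(5,4)/C(10,4) = 5/210
    expect_equal(pValues(cur)[1], 5 / 210, tolerance = 1e-12)
    # saturation: K = N forces k = n and p = 1
    expect_equal(pValues(cur)[2], 1)
    expect_equal(observedCounts(cur)[2], 4)
    expect_error(proximityEnrichmentScan(c("gX"), genes, regs),
                 "consistency")
    # K and k are non-decreasing in x by construction
    set.seed(33)
    genes2 <- data.frame(gene_id = paste0("h", 1:100), chrom = "chr1",
                         tss = sample(0:49999, 100), strand = "+")
    regs2 <- GenomicRanges::GRanges("chr1",
                                    IRanges::IRanges(c(1000, 30000),
                                                     width = 500))
    cur2 <- proximityEnrichmentScan(paste0("h", 1:20), genes2, regs2)
    expect_true(all(diff(curveMeta(cur2)$K) >= 0))
    expect_true(all(diff(observedCounts(cur2)) >= 0))
})

test_that("curve containers validate and print", {
    cur <- poissonEnrichment(c(1, 2), c(1, 1), grid = c(5, 15))
    df <- as.data.frame(cur)
    expect_identical(colnames(df), c("distance", "observed", "expected",
                                     "pvalue", "neglog10p"))
    expect_output(show(cur), "EnrichmentCurve")
    expect_error(new("EnrichmentCurve", grid = c(1, 2), observed = 1,
                     expected = c(1, 1), pvalue = c(0.5, 0.5),
                     neglog10p = c(0.3, 0.3), meta = list()),
                 "equal length")
})
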