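gr1 <- function(s, e) GenomicRanges::GRanges("chr1",
                                             IRanges::IRanges(s, e))

test_that("reproducible peaks: identity, sweep example, min = 1 union", {
    same <- list(gr1(1, 100), gr1(1, 100), gr1(1, 100))
    out <- reproduciblePeaks(same, 3)
    expect_equal(GenomicRanges::start(out), 1L)
    expect_equal(GenomicRanges::end(out), 100L)

    # staggered peaks: core = triple-covered run, span = union of the
    # contributing peaks (BED [0,100),[50,150),[60,90) in 1-based form)
    sets <- list(gr1(1, 100), gr1(51, 150), gr1(61, 90))
    out <- reproduciblePeaks(sets, 3)
    expect_equal(length(out), 1L)
    expect_equal(S4Vectors::mcols(out)$core_start, 61L)
    expect_equal(S4Vectors::mcols(out)$core_end, 90L)
    expect_equal(GenomicRanges::start(out), 1L)
    expect_equal(GenomicRanges::end(out), 150L)

    u <- reproduciblePeaks(sets, 1)
    expect_equal(GenomicRanges::start(u), 1L)
    expect_equal(GenomicRanges::end(u), 150L)
    expect_error(reproduciblePeaks(list(), 1), "at least one")
})

test_that("reproducible peaks agree with a base-coverage sweep oracle and
           are monotone in minReplicates", {
    set.seed(3)
    for (rep in 1:5) {
        sets <- lapply(1:4, function(i) {
            s <- sort(sample(1:500, 6))
            GenomicRanges::reduce(gr1(s, s + sample(10:60, 6,
                                                    replace = TRUE)))
        })
        cov <- rep(0L, 700)
        for (st in sets) for (j in seq_along(st)) {
            idx <- GenomicRanges::start(st)[j]:GenomicRanges::end(st)[j]
            cov[idx] <- cov[idx] + 1L
        }
        prev <- NULL
        for (minRep in 1:4) {
            out <- reproduciblePeaks(sets, minRep)
            # every retained core base is covered >= minRep times
            coreBases <- integer()
            if (length(out))
                for (j in seq_along(out))
                    coreBases <- c(coreBases,
                        S4Vectors::mcols(out)$core_start[j]:
                        S4Vectors::mcols(out)$core_end[j])
            expect_true(all(cov[coreBases] >= minRep))
            expect_equal(sort(unique(coreBases)), which(cov >= minRep))
            # monotone: raising the threshold never adds covered bases
            if (!is.null(prev))
                expect_true(all(coreBases %in% prev))
            prev <- if (length(coreBases)) coreBases else integer()
        }
    }
})

test_that("merged peak sets carry Venn flags matching brute-force overlap", {
    set.seed(8)
    sets <- lapply(1:3, function(i) {
        s <- sort(sample(1:3000, 30))
        GenomicRanges::reduce(gr1(s, s + 40))
    })
    names(sets) <- c("Esrrb", "Nr5a2", "Oct4")
    merged <- mergePeakSets(sets)
    expect_equal(length(GenomicRanges::reduce(merged)), length(merged))
    for (nm in names(sets)) {
        flag <- S4Vectors::mcols(merged)[[nm]]
        brute <- vapply(seq_along(merged), function(i) {
            any(GenomicRanges::start(sets[[nm]]) <=
                    GenomicRanges::end(merged)[i] &
                GenomicRanges::end(sets[[nm]]) >=
                    GenomicRanges::start(merged)[i])
        }, TRUE)
        expect_identical(unname(flag), brute)
    }
    vc <- vennCounts(merged)
    expect_equal(sum(vc$count), length(merged))
    # disjoint sets concatenate with one-hot flags
    dis <- mergePeakSets(list(a = gr1(1, 10), b = gr1(100, 110)))
    expect_equal(length(dis), 2L)
    expect_equal(sum(S4Vectors::mcols(dis)$a), 1L)
    # overlapping pair merges with both flags
    ov <- mergePeakSets(list(a = gr1(1, 100), b = gr1(51, 150)))
    expect_equal(length(ov), 1L)
    expect_true(all(unlist(S4Vectors::mcols(ov))))
})

test_that("blacklist exclusion removes any >= 1 bp overlap", {
    regions <- c(gr1(1, 100), gr1(200, 300), gr1(400, 500))
    expect_identical(excludeBlacklist(regions, GenomicRanges::GRanges()),
                     regions)
    bl <- gr1(300, 400)  # 1 bp overlap with both middle and last
    kept <- excludeBlacklist(regions, bl)
    expect_equal(GenomicRanges::start(kept), 1L)
    expect_equal(length(excludeBlacklist(gr1(350, 360), gr1(300, 400))),
                 0L)
})

test_that("normalisation scales by library size and refuses to repeat", {
    cnt <- matrix(c(100, 0, 50, 10), 2, 2,
                  dimnames = list(c("r1", "r2"), c("s1", "s2")))
    gr <- gr1(c(1, 201), c(100, 300))
    names(gr) <- c("r1", "r2")
    si <- data.frame(tf = "Oct4", condition = "pp", replicate = 1:2)
    be <- BindingExperiment(cnt, gr, si, libSizes = c(1e6, 2e6))
    nb <- normaliseCounts(be, "per-million")
    expect_equal(normValues(nb)["r1", "s1"], 100)
    expect_equal(normValues(nb)["r1", "s2"], 25)
    expect_error(normaliseCounts(nb, "per-million"), "already")
    nb10 <- normaliseCounts(be, "per-ten-million")
    expect_equal(normValues(nb10)["r1", "s1"], 1000)
    # zero pattern and within-sample order preserved
    expect_identical(normValues(nb) == 0,
                     SummarizedExperiment::assay(be, "counts") == 0)
    expect_identical(order(normValues(nb)[, 1]), order(cnt[, 1]))
})

test_that("z-scoring uses the n-1 standard deviation and is location
           invariant", {
    expect_equal(zscoreFoldchanges(c(-1, 1)),
                 c(-1, 1) / sqrt(2), tolerance = 1e-12)
    x <- c(0.3, -1.2, 2.5, 0.1, 0.9)
    z <- zscoreFoldchanges(x)
    expect_equal(mean(z), 0, tolerance = 1e-12)
    expect_equal(stats::sd(z), 1, tolerance = 1e-12)
    expect_equal(zscoreFoldchanges(x + 5), z, tolerance = 1e-12)
    expect_error(zscoreFoldchanges(rep(1, 4)), "variance")
})

test_that("DE filter applies the three rules exactly", {
    res <- data.frame(unit_id = c("u1", "u2", "u3"),
                      log2fc = c(1, log2(1.5), -2),
                      fdr = c(0.001, 0.001, 0.001))
    cnt <- rbind(u1 = c(19, 25, 25, 30, 30, 30),
                 u2 = c(50, 50, 50, 50, 50, 50),
                 u3 = c(5, 5, 5, 5, 5, 5))
    cond <- rep(c("A", "B"), each = 3)
    out <- deFilter(res, cnt, cond)
    # u1 passes the count rule through condition B despite the 19 in A
    expect_true("u1" %in% out$unit_id)
    # FC exactly 1.5 is excluded (strict >)
    expect_false("u2" %in% out$unit_id)
    # all replicates below 20 in both conditions
    expect_false("u3" %in% out$unit_id)
    expect_identical(out$direction, "up")
})

test_that("DE filter equals brute-force rule application on a 500-unit
           table", {
    set.seed(19)
    n <- 500
    res <- data.frame(unit_id = sprintf("u%03d", 1:n),
                      log2fc = stats::rnorm(n, 0, 1.2),
                      fdr = stats::runif(n)^2)
    cnt <- matrix(stats::rnbinom(n * 6, mu = 25, size = 5), n,
                  dimnames = list(res$unit_id, NULL))
    cond <- rep(c("A", "B"), each = 3)
    out <- deFilter(res, cnt, cond)
    brute <- vapply(seq_len(n), function(i) {
        passA <- all(cnt[i, 1:3] >= 20)
        passB <- all(cnt[i, 4:6] >= 20)
        (passA || passB) && 2^abs(res$log2fc[i]) > 1.5 &&
            res$fdr[i] < 0.01
    }, TRUE)
    expect_setequal(out$unit_id, res$unit_id[brute])
})
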