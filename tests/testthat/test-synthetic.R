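test_that("background genome has the requested composition and is
           deterministic", {
    g <- generateGenome(2, 10000, gc = 0.5, seed = 1)
    expect_identical(names(g), c("chr1", "chr2"))
    gcCount <- sum(Biostrings::letterFrequency(g, "GC"))
    n <- 2 * 10000
    # within 3 sd of Binomial(n, 0.5)
    expect_lt(abs(gcCount - n * 0.5), 3 * sqrt(n * 0.25))
    expect_identical(as.character(generateGenome(2, 10000, 0.5, 1)),
                     as.character(g))
    expect_false(identical(as.character(generateGenome(2, 10000, 0.5, 2)),
                           as.character(g)))
    # boundary: gc = 0 is all A/T
    g0 <- generateGenome(1, 1000, gc = 0, seed = 3)
    expect_equal(sum(Biostrings::letterFrequency(g0, "GC")), 0)
    expect_error(generateGenome(1, 500, 0.5, 1), "chromLen")
    expect_error(generateGenome(1, 1000, 1.5, 1), "gc")
})

test_that("planted motifs are recovered exactly by rescanning", {
    g <- generateGenome(2, 2e5, 0.5, seed = 5)
    pl <- plantRegionsAndMotifs(g, nRegions = 300, regionLen = 400,
                                variantMix = list(c(T = 0.5, C = 0.5)),
                                seed = 9)
    expect_equal(length(pl$regions), 300L)
    expect_true(all(GenomicRanges::width(pl$regions) == 400))
    # non-overlapping regions
    expect_equal(length(GenomicRanges::reduce(pl$regions)), 300L)
    seqs <- regionSequences(pl$genome, pl$regions)
    hits <- scanTrimmedHalfsite(seqs, 0)
    plants <- pl$truth$motif_plants
    key <- function(d) paste(d$region_id, d$offset, d$strand)
    found <- key(plants) %in% key(hits)
    expect_gte(mean(found), 0.99)
    # variants recovered too
    m <- merge(plants, hits, by.x = c("region_id", "offset", "strand"),
               by.y = c("region_id", "offset", "strand"))
    expect_true(all(m$variant == m$seventh_base))
})

test_that("all-T variant mix plants only T seventh bases", {
    g <- generateGenome(1, 1e5, 0.5, seed = 2)
    pl <- plantRegionsAndMotifs(g, nRegions = 100, regionLen = 400,
                                variantMix = list(c(T = 1, C = 0)),
                                seed = 3)
    expect_true(all(pl$truth$motif_plants$variant == "T"))
})

test_that("zero-jitter Oct/Sox plants sit at exactly the requested centre
           distance", {
    g <- generateGenome(1, 3e5, 0.5, seed = 6)
    pl <- plantRegionsAndMotifs(g, nRegions = 300, regionLen = 400,
                                variantMix = list(c(T = 1, C = 0)),
                                octsoxSpacing = 50, octsoxFraction = 1,
                                octsoxJitter = 0, seed = 7)
    plants <- pl$truth$motif_plants
    seqs <- regionSequences(pl$genome, pl$regions)
    hs <- scanTrimmedHalfsite(seqs, 0)
    os <- scanConsensus(seqs, octSoxConsensus(), 0, motifName = "OctSox")
    both <- intersect(hs$region_id, os$region_id)
    expect_gt(length(both), 250)
    for (rid in both) {
        cH <- hs$offset[hs$region_id == rid] + 4
        cO <- os$offset[os$region_id == rid] + 7
        expect_true(any(abs(outer(cH, cO, "-")) == 50))
    }
})

test_that("region placement beyond capacity errors", {
    expect_error(plantRegionsAndMotifs(NULL, nRegions = 100,
                                       regionLen = 400,
                                       chromLens = c(chr1 = 10000),
                                       seed = 1),
                 "capacity")
})

test_that("simulated counts follow the planted effects", {
    ids <- sprintf("r%04d", 1:2000)
    truth <- list(region_class = stats::setNames(rep(1:2, each = 1000),
                                                 ids))
    be <- simulateCounts(truth, sampleSheet("Oct4", c("pp", "dEN"), 3),
                         effects = plantedEffects(2, c(0, -2)), seed = 21)
    cnt <- SummarizedExperiment::assay(be, "counts")
    cd <- as.data.frame(SummarizedExperiment::colData(be))
    libf <- S4Vectors::metadata(be)$libFactors
    adj <- sweep(cnt, 2, libf, "/")
    mPP <- rowMeans(adj[, cd$condition == "pp"])
    mEN <- rowMeans(adj[, cd$condition == "dEN"])
    cls <- truth$region_class
    # law of large numbers: mean ratio ~ 2^-2 for planted, ~1 for null
    expect_equal(mean(mEN[cls == 2]) / mean(mPP[cls == 2]), 0.25,
                 tolerance = 0.05)
    expect_equal(mean(mEN[cls == 1]) / mean(mPP[cls == 1]), 1,
                 tolerance = 0.05)
    # determinism
    be2 <- simulateCounts(truth, sampleSheet("Oct4", c("pp", "dEN"), 3),
                          effects = plantedEffects(2, c(0, -2)), seed = 21)
    expect_identical(cnt, SummarizedExperiment::assay(be2, "counts"))
    expect_error(simulateCounts(truth, sampleSheet("Oct4", "pp", 2),
                                alpha = 0), "dispersion")
    # missing effect entries are an error
    expect_error(simulateCounts(truth,
                                sampleSheet("Sox2", c("pp", "dEN"), 2),
                                effects = plantedEffects(2, 0, "Oct4")),
                 "effects missing")
})

test_that("gene links respect distance, fraction 1 and determinism", {
    regs <- placeRegions <- plantRegionsAndMotifs(
        NULL, nRegions = 200, regionLen = 400,
        classProps = c(0.5, 0.5), chromLens = c(chr1 = 5e6, chr2 = 5e6),
        seed = 4)$regions
    gd <- simulateGenesAndDe(regs, c(chr1 = 5e6, chr2 = 5e6),
                             nGenes = 300, deSetSizes = c("1" = 50),
                             linkDistance = 1000, linkFraction = 1,
                             seed = 5)
    linked <- gd$deSets[["1"]]
    cls1 <- regs[S4Vectors::mcols(regs)$class == 1]
    within <- genesWithin(gd$genes, cls1, 1000)
    expect_true(all(linked %in% within))
    gd2 <- simulateGenesAndDe(regs, c(chr1 = 5e6, chr2 = 5e6),
                              nGenes = 300, deSetSizes = c("1" = 50),
                              linkDistance = 1000, linkFraction = 1,
                              seed = 5)
    expect_identical(gd$genes, gd2$genes)
    expect_identical(gd$de, gd2$de)
    # planted DE genes satisfy the fold-change and FDR thresholds
    de <- gd$de[gd$de$response_class != "ns", ]
    expect_true(all(2^abs(de$log2fc) > 1.5))
    expect_true(all(de$fdr < 0.01))
})

test_that("study presets are reproducible and differ across seeds", {
    a <- syntheticStudy("null", seed = 1, nRegions = 50)
    b <- syntheticStudy("null", seed = 1, nRegions = 50)
    expect_identical(as.character(a$genome), as.character(b$genome))
    expect_identical(a$truth$region_class, b$truth$region_class)
    c <- syntheticStudy("null", seed = 2, nRegions = 50)
    expect_false(identical(as.character(a$genome),
                           as.character(c$genome)))
})
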