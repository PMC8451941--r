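# Deterministic synthetic-study generator with planted ground truth:
# background genome, non-overlapping regions carrying planted half-site
# variants (and optionally a composite Oct/Sox element at a controlled
# spacing), negative-binomial region x sample counts with class- and
# condition-dependent effects, and genes whose TSS placement and
# differential-expression status are tied to region classes.

#' Composite Oct/Sox consensus planted by the generator
#' @return a 15-bp character scalar.
#' @export
octSoxConsensus <- function() "CATTGTTATGCAAAT"

#' Simulate an i.i.d. background genome
#'
#' @param nChroms number of chromosomes (default 2).
#' @param chromLen chromosome length in bp (>= 1000; default 1e6).
#' @param gc GC fraction in \[0, 1\] (default 0.5).
#' @param seed integer seed; identical parameters and seed give an
#'   identical genome.
#' @return a named `DNAStringSet` (chr1, chr2, ...).
#' @examples
#' g <- generateGenome(1, 1000, gc = 0, seed = 1)
#' Biostrings::letterFrequency(g, "GC")
#' @export
generateGenome <- function(nChroms = 2L, chromLen = 1e6, gc = 0.5,
                           seed = 1L) {
    if (chromLen < 1000) stop("'chromLen' must be >= 1000")
    if (gc < 0 || gc > 1) stop("'gc' must lie in [0, 1]")
    prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    seqs <- withSeed(seed, {
        vapply(seq_len(nChroms), function(i)
            paste(DNA_BASES[sample.int(4L, chromLen, replace = TRUE,
                                       prob = prob)], collapse = ""),
            "")
    })
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- paste0("chr", seq_len(nChroms))
    out
}

# Random non-overlapping region placement over the given chromosome
# lengths (stars-and-bars: gaps drawn uniformly). Errors when capacity is
# exceeded.
placeRegions <- function(chromLens, nRegions, regionLen, seed) {
    stopifnot(!is.null(names(chromLens)))
    chromLens <- stats::setNames(as.numeric(chromLens), names(chromLens))
    nRegions <- as.numeric(nRegions)
    total <- sum(chromLens)
    if (nRegions * regionLen > total)
        stop("capacity error: ", nRegions, " regions of ", regionLen,
             " bp do not fit in ", total, " bp")
    perChrom <- floor(nRegions * chromLens / total)
    i <- 1L
    while (sum(perChrom) < nRegions) {
        perChrom[i] <- perChrom[i] + 1L
        i <- i %% length(chromLens) + 1L
    }
    if (any(perChrom * regionLen > chromLens))
        stop("capacity error: regions do not fit on every chromosome")
    withSeed(seed, {
        grl <- lapply(names(chromLens), function(chr) {
            k <- perChrom[[chr]]
            if (k == 0L) return(NULL)
            extra <- chromLens[[chr]] - k * regionLen
            u <- sort(floor(stats::runif(k, 0, extra + 1)))
            start0 <- u + (seq_len(k) - 1L) * regionLen
            GenomicRanges::GRanges(chr, IRanges::IRanges(start0 + 1L,
                                                         width = regionLen))
        })
        gr <- unlist(GenomicRanges::GRangesList(
            grl[!vapply(grl, is.null, TRUE)]))
        ids <- sprintf("reg%05d", seq_along(gr))
        names(gr) <- ids
        mcols(gr)$id <- ids
        gr
    })
}

# non-overlapping offsets for nSites motifs of width w in [edge, L-w-edge]
drawSiteOffsets <- function(nSites, L, w, edge, tries = 50L) {
    lo <- edge; hi <- L - w - edge
    if (hi < lo) stop("region too short for motif planting")
    for (t in seq_len(tries)) {
        off <- sort(floor(stats::runif(nSites, lo, hi + 1)))
        if (nSites == 1L || all(diff(off) >= w + 2L)) return(off)
    }
    stop("could not place ", nSites, " non-overlapping sites")
}

#' Plant regions and motifs into a genome
#'
#' Places `nRegions` non-overlapping regions of `regionLen` bp, assigns
#' each a class, and (optionally) writes half-site variant motifs — and a
#' composite Oct/Sox element at a controlled centre-to-centre spacing —
#' into the genome sequence at recorded offsets and strands. Planted
#' strings overwrite the background so the truth is unambiguous.
#'
#' @param genome `DNAStringSet` from [generateGenome()], or `NULL` to
#'   place coordinates only (requires `chromLens`).
#' @param nRegions,regionLen number and width (>= 200 bp) of regions.
#' @param classProps per-class proportions, summing to 1 (default one
#'   class).
#' @param variantMix seventh-base variant scheme: `NULL` (no motifs
#'   planted), a list with one `c(T = , C = )` probability pair per class,
#'   or `"gradient"` (P(C) rises linearly from 0 to 1 along the region
#'   index).
#' @param octsoxSpacing centre-to-centre distance (bp) at which the
#'   Oct/Sox consensus is planted next to the first half-site, or `NULL`.
#' @param octsoxFraction fraction of motif-bearing regions receiving the
#'   Oct/Sox plant (default 0.3).
#' @param octsoxJitter uniform jitter (+/- bp) on the spacing (default 5).
#' @param siteCountProbs named probabilities for the number of half-sites
#'   per region, e.g. `c("1" = 0.8, "2" = 0.2)`.
#' @param edge margin (bp) kept free at both region ends (default 20).
#' @param chromLens named chromosome lengths, needed when `genome` is
#'   `NULL`.
#' @param seed integer seed.
#' @return list: `genome` (edited, or `NULL`), `regions` (named
#'   `GRanges`), `truth` (list: `region_class` named integer vector,
#'   `motif_plants` data.frame, `planted_spacing`, `seed`).
#' @export
plantRegionsAndMotifs <- function(genome, nRegions = 2000L,
                                  regionLen = 400L, classProps = 1,
                                  variantMix = NULL, octsoxSpacing = NULL,
                                  octsoxFraction = 0.3, octsoxJitter = 5L,
                                  siteCountProbs = c("1" = 1),
                                  edge = 20L, chromLens = NULL, seed = 1L) {
    if (regionLen < 200L) stop("'regionLen' must be >= 200 bp")
    if (abs(sum(classProps) - 1) > 1e-8)
        stop("'classProps' must sum to 1")
    if (is.null(genome) && is.null(chromLens))
        stop("either 'genome' or 'chromLens' is required")
    if (!is.null(genome))
        chromLens <- stats::setNames(Biostrings::width(genome),
                                     names(genome))
    regions <- placeRegions(chromLens, nRegions,
                            regionLen, deriveSeed(seed, "place"))
    nClasses <- length(classProps)
    hsW <- nchar(halfsiteT())
    osW <- nchar(octSoxConsensus())
    res <- withSeed(deriveSeed(seed, "plant"), {
        cls <- sample(rep(seq_len(nClasses),
                          times = diff(round(cumsum(c(0, classProps)) *
                                             nRegions))))
        length(cls) <- nRegions
        cls[is.na(cls)] <- nClasses
        plants <- list()
        for (i in seq_len(nRegions)) {
            if (is.null(variantMix)) break
            pC <- if (identical(variantMix, "gradient")) {
                if (nRegions > 1L) (i - 1) / (nRegions - 1) else 0.5
            } else {
                mix <- variantMix[[cls[i]]]
                mix[["C"]] / sum(mix)
            }
            nSites <- as.integer(sample(names(siteCountProbs), 1L,
                                        prob = siteCountProbs))
            off <- drawSiteOffsets(nSites, regionLen, hsW, edge)
            variant <- ifelse(stats::runif(nSites) < pC, "C", "T")
            strand <- sample(c("+", "-"), nSites, replace = TRUE)
            plants[[length(plants) + 1L]] <- data.frame(
                region_id = names(regions)[i],
                motif_name = halfsiteTrimmed(), offset = off,
                strand = strand, variant = variant, width = hsW,
                stringsAsFactors = FALSE)
            if (!is.null(octsoxSpacing) &&
                stats::runif(1L) < octsoxFraction) {
                d <- octsoxSpacing + sample(seq(-octsoxJitter,
                                                octsoxJitter), 1L)
                cHS <- off[1L] + floor(hsW / 2)
                side <- sample(c(-1L, 1L), 1L)
                for (s in c(side, -side)) {
                    cOS <- cHS + s * d
                    offOS <- cOS - floor(osW / 2)
                    ok <- offOS >= 0L && offOS + osW <= regionLen &&
                        all(abs(cOS - (off + floor(hsW / 2))) >=
                            (hsW + osW) / 2 + 1)
                    if (ok) {
                        plants[[length(plants) + 1L]] <- data.frame(
                            region_id = names(regions)[i],
                            motif_name = "OctSox", offset = offOS,
                            strand = sample(c("+", "-"), 1L),
                            variant = NA_character_, width = osW,
                            stringsAsFactors = FALSE)
                        break
                    }
                }
            }
        }
        list(cls = cls, plants = do.call(rbind, c(plants, list(
            data.frame(region_id = character(), motif_name = character(),
                       offset = integer(), strand = character(),
                       variant = character(), width = integer(),
                       stringsAsFactors = FALSE)))))
    })
    mcols(regions)$class <- res$cls
    if (!is.null(genome) && nrow(res$plants)) {
        pl <- res$plants
        pl$string <- vapply(seq_len(nrow(pl)), function(i) {
            s <- if (pl$motif_name[i] == "OctSox") octSoxConsensus()
                 else if (pl$variant[i] == "C") halfsiteC() else halfsiteT()
            if (pl$strand[i] == "-") reverseComplement1(s) else s
        }, "")
        regIdx <- match(pl$region_id, names(regions))
        chrom <- as.character(GenomicRanges::seqnames(regions))[regIdx]
        absStart <- GenomicRanges::start(regions)[regIdx] + pl$offset
        for (chr in unique(chrom)) {
            j <- which(chrom == chr)
            genome[[chr]] <- Biostrings::replaceAt(
                genome[[chr]],
                IRanges::IRanges(absStart[j], width = pl$width[j]),
                Biostrings::DNAStringSet(pl$string[j]))
        }
    }
    truth <- list(region_class = stats::setNames(res$cls, names(regions)),
                  motif_plants = res$plants,
                  planted_spacing = octsoxSpacing, seed = seed)
    list(genome = genome, regions = regions, truth = truth)
}

#' Sample sheet helper
#'
#' @param tfs,conditions,nReps factors of the design; expanded in the
#'   order replicate-within-condition-within-TF.
#' @return data.frame with `tf`, `condition`, `replicate` and rownames
#'   `TF_condition_rep`.
#' @export
sampleSheet <- function(tfs, conditions, nReps) {
    d <- expand.grid(replicate = seq_len(nReps), condition = conditions,
                     tf = tfs, stringsAsFactors = FALSE)[, 3:1]
    rownames(d) <- paste(d$tf, d$condition, d$replicate, sep = "_")
    d
}

#' Planted effect table helper
#'
#' Builds the long-format `(class, tf, condition) -> log2fc` table that
#' [simulateCounts()] consumes; the baseline condition `"pp"` is implicit
#' (effect 0).
#'
#' @param nClasses number of classes (effects recycled across them).
#' @param log2fc planted log2 fold change(s).
#' @param tfs,conditions design labels.
#' @return data.frame `class`, `tf`, `condition`, `log2fc`.
#' @export
plantedEffects <- function(nClasses = 1L, log2fc = 0, tfs = "Oct4",
                           conditions = "dEN") {
    d <- expand.grid(class = seq_len(nClasses), tf = tfs,
                     condition = conditions, stringsAsFactors = FALSE)
    d$log2fc <- rep_len(log2fc, nrow(d))
    d
}

#' Default dependence-class effects of the synthetic study
#'
#' Five occupancy classes for the pluripotency factors (Oct4, Sox2,
#' Nanog), emulating the dependence structure of interest: class 1 loses
#' binding upon Esrrb depletion, class 2 upon Nr5a2 depletion, class 3
#' only upon the double depletion (with a greater-than-additive component:
#' the double effect exceeds the sum of the singles by 1 log2 unit),
#' class 4 upon either, and class 5 gains binding. The ChIPped receptors
#' themselves collapse in their own depletion conditions.
#'
#' @return effects data.frame as for [simulateCounts()].
#' @export
defaultClassEffects <- function() {
    pl <- rbind(
        data.frame(class = 1L, dE = -2,    dN = 0,     dEN = -2),
        data.frame(class = 2L, dE = 0,     dN = -2,    dEN = -2),
        data.frame(class = 3L, dE = -0.75, dN = -0.75, dEN = -2.5),
        data.frame(class = 4L, dE = -1.5,  dN = -1.5,  dEN = -3),
        data.frame(class = 5L, dE = 1,     dN = 1,     dEN = 2))
    rows <- list()
    for (tf in c("Oct4", "Sox2", "Nanog"))
        for (cond in c("dE", "dN", "dEN"))
            rows[[length(rows) + 1L]] <- data.frame(
                class = pl$class, tf = tf, condition = cond,
                log2fc = pl[[cond]])
    for (cond in c("dE", "dN", "dEN")) {
        rows[[length(rows) + 1L]] <- data.frame(
            class = 1:5, tf = "Esrrb", condition = cond,
            log2fc = if (cond == "dN") 0 else -3)
        rows[[length(rows) + 1L]] <- data.frame(
            class = 1:5, tf = "Nr5a2", condition = cond,
            log2fc = if (cond == "dE") 0 else -3)
    }
    do.call(rbind, rows)
}

#' Simulate negative-binomial region-by-sample counts
#'
#' Counts are drawn NB with variance `mu + alpha * mu^2` and mean
#' `baselineMean * libFactor_s * 2^(effect(class_r, tf_s, cond_s) +
#' ratio_r(tf_s))`, where the optional per-region `ratio_effect` adds
#' `+r/2` to Esrrb and `-r/2` to Nr5a2 means (the seventh-base binding
#' preference). The baseline condition is `"pp"` (effect 0).
#'
#' @param truth list with `region_class` (named integer vector); an
#'   optional `ratio_effect` named numeric vector and optional `regions`
#'   `GRanges` are used when present.
#' @param samples data.frame from [sampleSheet()].
#' @param effects effect table ([plantedEffects()] /
#'   [defaultClassEffects()]); `NULL` means no effects anywhere. Every
#'   (class, tf, non-baseline condition) combination present in the design
#'   must be covered.
#' @param baselineMean expected baseline count per region (default 100).
#' @param alpha NB dispersion (> 0, default 0.1).
#' @param libFactorRange sample library-size factors are drawn uniformly
#'   from this range (default 0.8-1.2).
#' @param seed integer seed.
#' @return a [BindingExperiment-class]; `metadata()$libFactors` records
#'   the drawn factors.
#' @export
simulateCounts <- function(truth, samples, effects = NULL,
                           baselineMean = 100, alpha = 0.1,
                           libFactorRange = c(0.8, 1.2), seed = 1L) {
    if (alpha <= 0) stop("'alpha' (NB dispersion) must be positive")
    cls <- truth$region_class
    nR <- length(cls)
    nS <- nrow(samples)
    eff <- matrix(0, nR, nS)
    if (!is.null(effects)) {
        need <- unique(data.frame(class = rep(unique(cls), each = nS),
                                  tf = samples$tf,
                                  condition = samples$condition))
        need <- need[need$condition != "pp", ]
        key <- function(d) paste(d$class, d$tf, d$condition)
        miss <- setdiff(key(need), key(effects))
        if (length(miss))
            stop("effects missing for (class, tf, condition): ",
                 paste(utils::head(miss, 3L), collapse = "; "))
        for (j in seq_len(nS)) {
            if (samples$condition[j] == "pp") next
            e <- effects[effects$tf == samples$tf[j] &
                         effects$condition == samples$condition[j], ]
            eff[, j] <- e$log2fc[match(cls, e$class)]
        }
    }
    if (!is.null(truth$ratio_effect)) {
        r <- truth$ratio_effect[names(cls)]
        r[is.na(r)] <- 0
        isE <- samples$tf == "Esrrb"
        isN <- samples$tf == "Nr5a2"
        eff[, isE] <- eff[, isE] + r / 2
        eff[, isN] <- eff[, isN] - r / 2
    }
    withSeed(seed, {
        libf <- stats::runif(nS, libFactorRange[1L], libFactorRange[2L])
        mu <- baselineMean * sweep(2^eff, 2L, libf, "*")
        cnt <- matrix(stats::rnbinom(nR * nS, mu = mu, size = 1 / alpha),
                      nR, nS)
        dimnames(cnt) <- list(names(cls), rownames(samples))
        regions <- truth$regions
        if (is.null(regions)) {
            regions <- GenomicRanges::GRanges(
                "chrU", IRanges::IRanges((seq_len(nR) - 1L) * 1000L + 1L,
                                         width = 400L))
            names(regions) <- names(cls)
        }
        be <- BindingExperiment(cnt, regions, samples,
                                libSizes = round(1e6 * libf))
        metadata(be)$libFactors <- stats::setNames(libf, rownames(samples))
        be
    })
}

#' Simulate genes, TSS placement and a differential-expression table
#'
#' Creates `nGenes` genes; for each response class named in `deSetSizes`,
#' that many genes are marked differentially expressed with the class's
#' direction, and — when the class is in `linkClasses` — a `linkFraction`
#' of them has its TSS placed within `linkDistance` bp of a randomly
#' chosen region of that class. All remaining genes (and the DE genes of
#' unlinked classes) are placed uniformly. A raw count matrix (two
#' conditions, `nReps` replicates) consistent with the planted fold
#' changes is included so count-based filters can be exercised.
#'
#' @param regions named `GRanges` with a `class` mcol.
#' @param chromLens named chromosome lengths.
#' @param nGenes total genes (default 1000).
#' @param deSetSizes named integer vector: DE genes per response class
#'   (names = class labels as character).
#' @param deDirections named `+1`/`-1` per response class (default: -1,
#'   i.e. down upon depletion).
#' @param linkClasses classes whose DE genes are linked (default: all in
#'   `deSetSizes`).
#' @param linkDistance,linkFraction proximity link parameters (defaults
#'   5000 bp, 0.8).
#' @param nReps replicates per condition in the count matrix (default 3).
#' @param alpha NB dispersion of the counts (default 0.1).
#' @param seed integer seed.
#' @return list: `genes` (gene table), `de` (full DE table with planted
#'   `log2fc`, `fdr`, `response_class`), `deSets` (named list of DE gene
#'   ids per class), `counts`, `conditions`, `truth` (per-gene link
#'   data.frame).
#' @export
simulateGenesAndDe <- function(regions, chromLens, nGenes = 1000L,
                               deSetSizes = c("1" = 60), deDirections = NULL,
                               linkClasses = names(deSetSizes),
                               linkDistance = 5000, linkFraction = 0.8,
                               nReps = 3L, alpha = 0.1, seed = 1L) {
    if (linkDistance <= 0) stop("'linkDistance' must be positive")
    if (is.null(deDirections))
        deDirections <- stats::setNames(rep(-1, length(deSetSizes)),
                                        names(deSetSizes))
    nDe <- sum(deSetSizes)
    stopifnot(nDe <= nGenes)
    withSeed(seed, {
        gid <- sprintf("gene%05d", seq_len(nGenes))
        chrom <- sample(names(chromLens), nGenes, replace = TRUE,
                        prob = chromLens / sum(chromLens))
        tss <- floor(stats::runif(nGenes, 0, chromLens[chrom]))
        strand <- sample(c("+", "-"), nGenes, replace = TRUE)
        respClass <- rep("ns", nGenes)
        linked <- rep(NA_character_, nGenes)
        log2fc <- stats::rnorm(nGenes, 0, 0.2)
        fdr <- stats::runif(nGenes, 0.02, 1)
        regClass <- as.character(mcols(regions)$class)
        gi <- 0L
        for (cl in names(deSetSizes)) {
            sz <- deSetSizes[[cl]]
            idx <- gi + seq_len(sz)
            gi <- gi + sz
            respClass[idx] <- cl
            dirn <- deDirections[[cl]]
            log2fc[idx] <- dirn * (log2(1.5) + 0.05 +
                                   stats::rexp(sz, rate = 2))
            fdr[idx] <- 10^stats::runif(sz, -8, -3)
            if (!cl %in% linkClasses) next
            nLink <- round(linkFraction * sz)
            cand <- which(regClass == cl)
            if (!length(cand)) stop("no regions of class ", cl, " to link")
            for (g in idx[seq_len(nLink)]) {
                ri <- cand[sample.int(length(cand), 1L)]
                s0 <- GenomicRanges::start(regions)[ri] - 1L
                e0 <- GenomicRanges::end(regions)[ri]
                chr <- as.character(GenomicRanges::seqnames(regions))[ri]
                d <- floor(stats::runif(1L, 0, linkDistance + 1))
                pos <- if (d == 0) floor(stats::runif(1L, s0, e0))
                       else if (stats::runif(1L) < 0.5) s0 - d
                       else e0 - 1L + d
                if (pos < 0 || pos >= chromLens[[chr]])
                    pos <- if (d == 0) s0 else
                        max(0L, min(chromLens[[chr]] - 1L,
                                    if (pos < 0) e0 - 1L + d else s0 - d))
                chrom[g] <- chr
                tss[g] <- pos
                linked[g] <- names(regions)[ri]
            }
        }
        baseMean <- stats::rlnorm(nGenes, log(60), 1.2)
        mu1 <- matrix(baseMean, nGenes, nReps)
        mu2 <- matrix(baseMean * 2^log2fc * (respClass != "ns") +
                      baseMean * (respClass == "ns"), nGenes, nReps)
        cnt <- cbind(matrix(stats::rnbinom(nGenes * nReps, mu = mu1,
                                           size = 1 / alpha), nGenes),
                     matrix(stats::rnbinom(nGenes * nReps, mu = mu2,
                                           size = 1 / alpha), nGenes))
        conditions <- rep(c("pp", "dEN"), each = nReps)
        colnames(cnt) <- paste0(conditions, "_", rep(seq_len(nReps), 2L))
        rownames(cnt) <- gid
        genes <- data.frame(gene_id = gid, chrom = chrom,
                            tss = as.integer(tss), strand = strand,
                            stringsAsFactors = FALSE)
        de <- data.frame(gene = gid, log2fc = log2fc, fdr = fdr,
                         response_class = respClass,
                         stringsAsFactors = FALSE)
        deSets <- lapply(stats::setNames(nm = names(deSetSizes)),
                         function(cl) gid[respClass == cl])
        list(genes = genes, de = de, deSets = deSets, counts = cnt,
             conditions = conditions,
             truth = data.frame(gene = gid, linked_region = linked,
                                response_class = respClass,
                                stringsAsFactors = FALSE))
    })
}

#' Assemble a complete synthetic study
#'
#' One call producing every input the downstream stages need, under one
#' of four presets:
#' \describe{
#'   \item{null}{background-only regions (no planted motifs, no effects,
#'     no gene links) on a 2 x 1 Mb genome; the calibration condition.}
#'   \item{spacing}{one half-site per region, with the Oct/Sox composite
#'     planted at a 50 bp centre distance (+/- 5 bp jitter) in 30\% of the
#'     regions; 2 x 1 Mb genome.}
#'   \item{classes}{five equally sized occupancy classes with the default
#'     dependence effects, counts for five TFs x four conditions x three
#'     replicates, and five DE gene sets (60 genes each) all linked to
#'     their class within 5 kb; sparse coordinates (2 x 25 Mb), no
#'     sequence.}
#'   \item{full}{everything: sequence on 2 x 25 Mb with a seventh-base
#'     T-to-C gradient along regions, one or two half-sites per region,
#'     Oct/Sox spacing plants, the class effects (with the
#'     greater-than-additive class-3 double depletion), seventh-base
#'     binding-ratio effects on Esrrb/Nr5a2, and gene links for classes
#'     1-4 with class 5 as an unlinked decoy.}
#' }
#'
#' @param preset one of `"null"`, `"spacing"`, `"classes"`, `"full"`.
#' @param seed integer master seed; every stage seed derives from it.
#' @param nRegions,regionLen,nGenes scale overrides.
#' @return list with (depending on preset) `genome`, `regions`, `truth`,
#'   `be` (counts), `samples`, `genes`, `de`, `deSets`, `geneCounts`,
#'   `geneConditions`, `effects`, `preset`, `seed`.
#' @export
syntheticStudy <- function(preset = c("null", "spacing", "classes", "full"),
                           seed = 1L, nRegions = 2000L, regionLen = 400L,
                           nGenes = 1000L) {
    preset <- match.arg(preset)
    out <- list(preset = preset, seed = seed)
    if (preset %in% c("null", "spacing")) {
        genome <- generateGenome(2L, 1e6, 0.5, deriveSeed(seed, "genome"))
        pl <- plantRegionsAndMotifs(
            genome, nRegions, regionLen,
            variantMix = if (preset == "spacing")
                list(c(T = 0.5, C = 0.5)) else NULL,
            octsoxSpacing = if (preset == "spacing") 50L else NULL,
            octsoxFraction = 0.3, octsoxJitter = 5L,
            siteCountProbs = c("1" = 1),
            seed = deriveSeed(seed, "plant"))
        out$genome <- pl$genome
        out$regions <- pl$regions
        out$truth <- pl$truth
        return(out)
    }
    chromLens <- c(chr1 = 25e6, chr2 = 25e6)
    useSeq <- preset == "full"
    genome <- if (useSeq)
        generateGenome(2L, 25e6, 0.5, deriveSeed(seed, "genome")) else NULL
    pl <- plantRegionsAndMotifs(
        genome, nRegions, regionLen, classProps = rep(0.2, 5L),
        variantMix = if (useSeq) "gradient" else NULL,
        octsoxSpacing = if (useSeq) 50L else NULL,
        octsoxFraction = 0.3, octsoxJitter = 5L,
        siteCountProbs = if (useSeq) c("1" = 0.8, "2" = 0.2) else c("1" = 1),
        chromLens = chromLens, seed = deriveSeed(seed, "plant"))
    truth <- pl$truth
    truth$regions <- pl$regions
    if (useSeq) {
        mp <- truth$motif_plants
        hs <- mp[mp$motif_name == halfsiteTrimmed(), ]
        fT <- tapply(hs$variant == "T", hs$region_id, mean)
        r <- stats::setNames(rep(0, nRegions), names(pl$regions))
        r[names(fT)] <- 1.5 * (2 * fT - 1)
        truth$ratio_effect <- r
    }
    effects <- defaultClassEffects()
    samples <- sampleSheet(c("Esrrb", "Nr5a2", "Oct4", "Sox2", "Nanog"),
                           c("pp", "dE", "dN", "dEN"), 3L)
    be <- simulateCounts(truth, samples, effects,
                         seed = deriveSeed(seed, "counts"))
    deSetSizes <- stats::setNames(rep(60L, 5L), as.character(1:5))
    deDirections <- c("1" = -1, "2" = -1, "3" = -1, "4" = -1, "5" = 1)
    linkClasses <- if (preset == "full") as.character(1:4)
                   else as.character(1:5)
    gd <- simulateGenesAndDe(pl$regions, chromLens, nGenes,
                             deSetSizes = deSetSizes,
                             deDirections = deDirections,
                             linkClasses = linkClasses,
                             linkDistance = 5000, linkFraction = 0.8,
                             seed = deriveSeed(seed, "genes"))
    out$genome <- pl$genome
    out$regions <- pl$regions
    out$truth <- truth
    out$effects <- effects
    out$samples <- samples
    out$be <- be
    out$genes <- gd$genes
    out$de <- gd$de
    out$deSets <- gd$deSets
    out$geneCounts <- gd$counts
    out$geneConditions <- gd$conditions
    out$geneTruth <- gd$truth
    out
}
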