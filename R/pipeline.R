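# End-to-end orchestration: one config, staged outputs, deterministic
# derived seeds, a digest manifest, and resume support.

#' Extract region sequences from a genome
#'
#' @param genome named `DNAStringSet`.
#' @param regions named `GRanges` on the genome's chromosomes.
#' @return `DNAStringSet` named by region id, in region order.
#' @export
regionSequences <- function(genome, regions) {
    chrom <- as.character(GenomicRanges::seqnames(regions))
    bad <- setdiff(unique(chrom), names(genome))
    if (length(bad))
        stop("regions on unknown chromosome(s): ",
             paste(bad, collapse = ", "))
    out <- character(length(regions))
    for (chr in unique(chrom)) {
        i <- which(chrom == chr)
        v <- Biostrings::Views(genome[[chr]],
                               GenomicRanges::start(regions)[i],
                               GenomicRanges::end(regions)[i])
        out[i] <- as.character(v)
    }
    stats::setNames(Biostrings::DNAStringSet(out), names(regions))
}

pipelineStages <- c("simulate", "scan", "diff", "classify", "pairdist",
                    "proximity", "trend", "coop")

logMsg <- function(level, threshold, ...) {
    levels <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)
    if (levels[[level]] >= levels[[threshold]])
        message(sprintf("[%s] %s", level, paste0(...)))
}

#' Run the synthetic-study pipeline end to end
#'
#' Executes the stages simulate, scan, diff, classify, pairdist,
#' proximity, trend and coop in dependency order on a synthetic preset,
#' writing every intermediate as a TSV (or FASTA/BED) under
#' `config$outdir` and returning a manifest of output digests. Stages
#' that do not apply to the chosen preset (e.g. `scan` for a preset
#' without sequence) are skipped with a note. Outputs are deterministic
#' given the config: per-stage seeds derive from the single top-level
#' seed and floating-point values are written with fixed precision, so
#' re-running an identical config reproduces identical file digests.
#'
#' With `resume = TRUE`, the pipeline finds the first stage with a
#' missing output file, reloads the earlier stages' results from disk,
#' and recomputes only from that stage onwards. On stage failure the
#' completed outputs are kept and an error manifest
#' (`manifest_error.tsv`) naming the failed stage is written before the
#' error propagates.
#'
#' @param config path to a YAML file, or an equivalent named list, with
#'   required keys `preset`, `seed`, `outdir` and optional keys `k`
#'   (classes for the classify stage, default 5), `shuffles`, `binWidth`,
#'   `maxDist`, `window`.
#' @param resume skip-and-reload completed leading stages (default
#'   `FALSE`).
#' @param logLevel one of `"debug"`, `"info"`, `"warn"`, `"error"`.
#' @return invisibly, a list with `manifest` (data.frame: stage, file,
#'   md5), `state` (the in-memory stage results) and `config`.
#' @export
runPipeline <- function(config, resume = FALSE, logLevel = "info") {
    if (is.character(config)) config <- yaml::read_yaml(config)
    need <- c("preset", "seed", "outdir")
    miss <- setdiff(need, names(config))
    if (length(miss))
        stop("config error: missing required key(s): ",
             paste(miss, collapse = ", "))
    if (!config$preset %in% c("null", "spacing", "classes", "full"))
        stop("config error: unknown preset '", config$preset, "'")
    getp <- function(key, default)
        if (is.null(config[[key]])) default else config[[key]]
    k <- getp("k", 5L)
    shuffles <- getp("shuffles", 100L)
    binWidth <- getp("binWidth", 10)
    maxDist <- getp("maxDist", 500)
    window <- getp("window", 100L)
    outdir <- config$outdir
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    seed <- as.integer(config$seed)
    manifest <- data.frame(stage = character(), file = character(),
                           md5 = character(), stringsAsFactors = FALSE)
    record <- function(stage, files) {
        files <- files[file.exists(files)]
        manifest <<- rbind(manifest, data.frame(
            stage = stage, file = basename(files),
            md5 = unname(tools::md5sum(files)), stringsAsFactors = FALSE))
    }
    p <- function(f) file.path(outdir, f)
    env <- new.env(parent = emptyenv())
    diffCombos <- rbind(
        expand.grid(tf = "Oct4", cond = c("dE", "dN", "dEN"),
                    stringsAsFactors = FALSE),
        expand.grid(tf = c("Sox2", "Nanog"), cond = "dEN",
                    stringsAsFactors = FALSE))
    hasSeq <- config$preset %in% c("null", "spacing", "full")
    hasCounts <- config$preset %in% c("classes", "full")

    # primary output(s) whose presence marks a stage as complete
    stageOutputs <- list(
        simulate = c("regions.bed", "truth_classes.tsv",
                     if (hasSeq) "genome.fa",
                     if (hasCounts) c("counts.tsv", "samples.tsv",
                                      "genes.tsv", "de.tsv")),
        scan = if (hasSeq) c("hits_halfsite.tsv", "hits_octsox.tsv"),
        diff = if (hasCounts)
            sprintf("diff_%s_%s.tsv", diffCombos$tf, diffCombos$cond),
        classify = if (hasCounts) "assignment.tsv",
        pairdist = if (hasSeq) "pairdist.tsv",
        proximity = if (hasCounts) "proximity_cluster1.tsv",
        trend = if (hasSeq && hasCounts) c("seventh_profile.tsv",
                                           "trend.tsv"),
        coop = if (hasSeq && hasCounts) "coop.tsv")

    stageRun <- list(
        simulate = function() {
            env$study <- syntheticStudy(config$preset, seed = seed)
            st <- env$study
            files <- character()
            if (!is.null(st$genome)) {
                writeFasta(st$genome, p("genome.fa"))
                files <- c(files, p("genome.fa"))
            }
            writeBed(st$regions, p("regions.bed"))
            writeTsv(data.frame(region_id = names(st$truth$region_class),
                                class = unname(st$truth$region_class)),
                     p("truth_classes.tsv"),
                     params = list(preset = st$preset, seed = seed))
            files <- c(files, p("regions.bed"), p("truth_classes.tsv"))
            if (nrow(st$truth$motif_plants)) {
                writeTsv(st$truth$motif_plants, p("truth_plants.tsv"))
                files <- c(files, p("truth_plants.tsv"))
            }
            if (!is.null(st$be)) {
                cnt <- assay(st$be, "counts")
                writeTsv(data.frame(region_id = rownames(cnt), cnt,
                                    check.names = FALSE), p("counts.tsv"))
                si <- cbind(sample_id = rownames(st$samples), st$samples,
                            lib_size = librarySizes(st$be))
                writeTsv(si, p("samples.tsv"))
                files <- c(files, p("counts.tsv"), p("samples.tsv"))
            }
            if (!is.null(st$genes)) {
                writeTsv(st$genes, p("genes.tsv"))
                writeTsv(st$de, p("de.tsv"))
                files <- c(files, p("genes.tsv"), p("de.tsv"))
            }
            record("simulate", files)
        },
        scan = function() {
            st <- env$study
            if (is.null(st$genome)) {
                logMsg("info", logLevel, "scan: no sequence, skipped")
                return()
            }
            seqs <- regionSequences(st$genome, st$regions)
            env$hitsHS <- scanTrimmedHalfsite(seqs, maxMismatch = 1L)
            env$hitsOS <- scanConsensus(seqs, octSoxConsensus(),
                                        maxMismatch = 2L,
                                        motifName = "OctSox")
            writeTsv(env$hitsHS, p("hits_halfsite.tsv"),
                     params = list(max_mismatch = 1))
            writeTsv(env$hitsOS, p("hits_octsox.tsv"),
                     params = list(max_mismatch = 2))
            record("scan", p(c("hits_halfsite.tsv", "hits_octsox.tsv")))
        },
        diff = function() {
            st <- env$study
            if (is.null(st$be)) {
                logMsg("info", logLevel, "diff: no counts, skipped")
                return()
            }
            env$diff <- list()
            files <- character()
            for (i in seq_len(nrow(diffCombos))) {
                tf <- diffCombos$tf[i]; cond <- diffCombos$cond[i]
                # the synthetic classes shift occupancy in most regions,
                # so anchor on the known library sizes rather than
                # median-of-ratios (which assumes a stable majority)
                res <- differentialTest(st$be, c("pp", cond), tf = tf,
                                        sizeFactors = "libsize")
                env$diff[[paste(tf, cond, sep = "_")]] <- res
                f <- p(sprintf("diff_%s_%s.tsv", tf, cond))
                writeTsv(res, f, params = list(tf = tf, contrast = cond))
                files <- c(files, f)
            }
            record("diff", files)
        },
        classify = function() {
            st <- env$study
            if (is.null(st$be)) {
                logMsg("info", logLevel, "classify: no counts, skipped")
                return()
            }
            nb <- normaliseCounts(st$be, "per-million")
            occ <- maxNormalise(occupancyMatrix(nb,
                                                c("Oct4", "Sox2", "Nanog")))
            env$occ <- occ
            env$km <- kmeansClasses(occ, k,
                                    seed = deriveSeed(seed, "kmeans"))
            writeTsv(env$km$assignment, p("assignment.tsv"),
                     params = list(k = k))
            record("classify", p("assignment.tsv"))
        },
        pairdist = function() {
            if (is.null(env$hitsHS)) {
                logMsg("info", logLevel, "pairdist: no hits, skipped")
                return()
            }
            st <- env$study
            w <- stats::setNames(GenomicRanges::width(st$regions),
                                 names(st$regions))
            curve <- pairDistanceEnrichment(
                env$hitsHS, env$hitsOS, w, nShuffles = shuffles,
                seed = deriveSeed(seed, "shuffle"), binWidth = binWidth,
                maxDist = maxDist)
            env$pairdist <- curve
            writeTsv(as.data.frame(curve), p("pairdist.tsv"),
                     params = list(shuffles = shuffles, bin = binWidth))
            record("pairdist", p("pairdist.tsv"))
        },
        proximity = function() {
            st <- env$study
            if (is.null(st$genes) || is.null(env$km)) {
                logMsg("info", logLevel, "proximity: no genes/classes, ",
                       "skipped")
                return()
            }
            deAll <- st$de$gene[st$de$response_class != "ns"]
            cls <- env$km$assignment
            files <- character()
            env$proximity <- list()
            for (ci in sort(unique(cls$class))) {
                regs <- st$regions[names(st$regions) %in%
                                   cls$region_id[cls$class == ci]]
                curve <- proximityEnrichmentScan(deAll, st$genes, regs)
                env$proximity[[ci]] <- curve
                f <- p(sprintf("proximity_cluster%d.tsv", ci))
                writeTsv(as.data.frame(curve), f,
                         params = list(cluster = ci))
                files <- c(files, f)
            }
            record("proximity", files)
        },
        trend = function() {
            st <- env$study
            if (is.null(env$hitsHS) || is.null(st$be)) {
                logMsg("info", logLevel, "trend: needs hits and counts, ",
                       "skipped")
                return()
            }
            nv <- sweep(assay(st$be, "counts"), 2L, librarySizes(st$be),
                        "/") * 1e6
            cd <- as.data.frame(colData(st$be))
            rpm <- function(tf) rowMeans(nv[, cd$tf == tf &
                                              cd$condition == "pp",
                                            drop = FALSE])
            ratio <- bindingRatio(rpm("Esrrb"), rpm("Nr5a2"))
            ranked <- names(sort(ratio, decreasing = TRUE))
            prof <- seventhBaseProfile(ranked, env$hitsHS, window = window)
            writeTsv(prof, p("seventh_profile.tsv"),
                     params = list(window = window))
            files <- p("seventh_profile.tsv")
            if (!is.null(env$diff$Oct4_dEN)) {
                fc <- stats::setNames(env$diff$Oct4_dEN$log2fc,
                                      env$diff$Oct4_dEN$unit_id)
                z <- zscoreFoldchanges(fc[ranked])
                # fit the trend on non-overlapping windows: independent
                # points, and an exact GP solve stays cheap
                tprof <- seventhBaseProfile(ranked, env$hitsHS,
                                            window = window,
                                            mode = "tiled")
                cs <- c(0, cumsum(z))
                wmean <- (cs[tprof$start_rank + window] -
                          cs[tprof$start_rank]) / window
                keep <- !is.na(tprof$freq_C)
                fit <- gpTrend(tprof$freq_C[keep], wmean[keep],
                               seed = deriveSeed(seed, "gp"))
                env$trend <- fit
                writeTsv(as.data.frame(fit), p("trend.tsv"))
                files <- c(files, p("trend.tsv"))
            }
            record("trend", files)
        },
        coop = function() {
            st <- env$study
            if (is.null(env$hitsHS) || is.null(env$diff$Oct4_dE)) {
                logMsg("info", logLevel, "coop: needs hits and Oct4 ",
                       "singles, skipped")
                return()
            }
            ss <- singleSiteRegions(env$hitsHS, names(st$regions))
            get <- function(nm) {
                d <- env$diff[[nm]]
                stats::setNames(d$log2fc, d$unit_id)[ss]
            }
            at <- additivityTest(get("Oct4_dE"), get("Oct4_dN"),
                                 get("Oct4_dEN"))
            env$coop <- at
            writeTsv(data.frame(n = at$n,
                                median_delta = stats::median(at$delta),
                                statistic = at$statistic,
                                pvalue = at$pvalue),
                     p("coop.tsv"), params = list(regions = "single-site"))
            record("coop", p("coop.tsv"))
        })

    hitCols <- c(offset = "integer", mismatches = "integer",
                 score = "numeric", width = "integer")
    stageLoad <- list(
        simulate = function() {
            st <- list(preset = config$preset, seed = seed)
            if (file.exists(p("genome.fa")))
                st$genome <- readFasta(p("genome.fa"))
            st$regions <- readBed(p("regions.bed"))
            tc <- readTsv(p("truth_classes.tsv"), c(class = "integer"))
            mcols(st$regions)$class <- tc$class[match(names(st$regions),
                                                      tc$region_id)]
            st$truth <- list(region_class = stats::setNames(
                tc$class, tc$region_id), motif_plants = data.frame())
            if (file.exists(p("counts.tsv"))) {
                cnt <- readCountsTable(p("counts.tsv"))
                si <- readTsv(p("samples.tsv"),
                              c(replicate = "integer",
                                lib_size = "numeric"))
                samples <- data.frame(tf = si$tf, condition = si$condition,
                                      replicate = si$replicate)
                rownames(samples) <- si$sample_id
                st$samples <- samples
                st$be <- BindingExperiment(cnt[, si$sample_id,
                                               drop = FALSE],
                                           st$regions, samples,
                                           libSizes = si$lib_size)
            }
            if (file.exists(p("genes.tsv"))) {
                st$genes <- readGeneTable(p("genes.tsv"))
                st$de <- readTsv(p("de.tsv"),
                                 c(gene = "character", log2fc = "numeric",
                                   fdr = "numeric",
                                   response_class = "character"))
            }
            env$study <- st
            record("simulate", p(stageOutputs$simulate))
        },
        scan = function() {
            if (!hasSeq) return()
            env$hitsHS <- readTsv(p("hits_halfsite.tsv"), hitCols)
            env$hitsOS <- readTsv(p("hits_octsox.tsv"), hitCols)
            record("scan", p(stageOutputs$scan))
        },
        diff = function() {
            if (!hasCounts) return()
            env$diff <- list()
            for (i in seq_len(nrow(diffCombos))) {
                nm <- paste(diffCombos$tf[i], diffCombos$cond[i], sep = "_")
                env$diff[[nm]] <- readTsv(p(sprintf("diff_%s.tsv", nm)),
                                          c(unit_id = "character",
                                            log2fc = "numeric",
                                            pvalue = "numeric",
                                            fdr = "numeric"))
            }
            record("diff", p(stageOutputs$diff))
        },
        classify = function() {
            if (!hasCounts) return()
            env$km <- list(assignment = readTsv(p("assignment.tsv"),
                                                c(region_id = "character",
                                                  class = "integer")))
            record("classify", p(stageOutputs$classify))
        })

    complete <- vapply(pipelineStages, function(s) {
        outs <- stageOutputs[[s]]
        length(outs) == 0L || all(file.exists(p(outs)))
    }, TRUE)
    firstMissing <- if (resume) {
        w <- which(!complete)
        if (length(w)) w[1L] else length(pipelineStages) + 1L
    } else 1L

    for (si in seq_along(pipelineStages)) {
        stage <- pipelineStages[si]
        loadable <- si < firstMissing
        fun <- if (loadable && !is.null(stageLoad[[stage]]))
            stageLoad[[stage]] else if (loadable) function() {
                record(stage, p(stageOutputs[[stage]]))
            } else stageRun[[stage]]
        if (loadable)
            logMsg("info", logLevel, "stage ", stage,
                   ": reusing existing outputs (resume)")
        else
            logMsg("info", logLevel, "stage ", stage, " ...")
        tryCatch(fun(), error = function(e) {
            err <- rbind(manifest,
                         data.frame(stage = stage, file = "<ERROR>",
                                    md5 = conditionMessage(e)))
            utils::write.table(err, p("manifest_error.tsv"), sep = "\t",
                               row.names = FALSE, quote = FALSE)
            stop("stage '", stage, "' failed: ", conditionMessage(e),
                 call. = FALSE)
        })
    }

    utils::write.table(manifest, p("manifest.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    logMsg("info", logLevel, "pipeline complete: ", nrow(manifest),
           " outputs in ", outdir)
    invisible(list(manifest = manifest, state = as.list(env),
                   config = config))
}
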