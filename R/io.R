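#' Read a FASTA file
#'
#' Reads DNA sequences with [Biostrings::readDNAStringSet()], folds them to
#' upper case, trims sequence names at the first whitespace and checks the
#' alphabet is restricted to A, C, G, T, N.
#'
#' @param path path to a FASTA file.
#' @return a named [Biostrings::DNAStringSet] (order as in the file).
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1 test", "acgt"), f)
#' as.character(readFasta(f))
#' @export
#' @importFrom Biostrings readDNAStringSet writeXStringSet DNAStringSet
#'   alphabetFrequency
readFasta <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    first <- readLines(path, n = 1L)
    if (length(first) == 0L)
        stop("FASTA format error: file is empty: ", path)
    if (!startsWith(first, ">"))
        stop("FASTA format error at line 1: expected '>' header, got: ",
             substr(first, 1L, 30L))
    x <- Biostrings::readDNAStringSet(path)
    if (length(x) == 0L) stop("FASTA format error: no records in ", path)
    names(x) <- sub("\\s.*$", "", names(x))
    x <- Biostrings::DNAStringSet(toupper(as.character(x)))
    af <- Biostrings::alphabetFrequency(x)
    bad <- rowSums(af[, !colnames(af) %in% c("A", "C", "G", "T", "N"),
                      drop = FALSE])
    if (any(bad > 0))
        stop("FASTA contains non-ACGTN letters in record(s): ",
             paste(names(x)[bad > 0], collapse = ", "))
    x
}

#' Write a FASTA file
#'
#' @param x named `DNAStringSet` or named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width, default 70.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(x, path, width = 70L) {
    if (!methods::is(x, "DNAStringSet"))
        x <- Biostrings::DNAStringSet(x)
    Biostrings::writeXStringSet(x, path, width = width)
    invisible(path)
}

#' Read peak intervals from a BED file
#'
#' Parses BED3/BED4 into a `GRanges`. BED coordinates are 0-based
#' half-open; the returned `GRanges` follows the usual 1-based closed
#' Bioconductor convention (start + 1). Column 4 provides the region id
#' when present, otherwise ids are synthesised as `"chrom:start-end"` in
#' BED coordinates. Input order is preserved and ids are set both as
#' `names()` and in `mcols()$id`.
#'
#' @param path path to a tab-separated BED file (>= 3 columns).
#' @return a named `GRanges`.
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines("chr1\t0\t100\tpkA", f)
#' readBed(f)
#' @export
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
readBed <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    lines <- readLines(path)
    keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
    lineno <- which(keep)
    lines <- lines[keep]
    if (length(lines) == 0L) stop("BED format error: no data lines in ", path)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    ncols <- lengths(parts)
    if (any(ncols < 3L))
        stop("BED format error at line ", lineno[which(ncols < 3L)[1L]],
             ": fewer than 3 tab-separated columns")
    chrom <- vapply(parts, `[[`, "", 1L)
    startc <- vapply(parts, `[[`, "", 2L)
    endc <- vapply(parts, `[[`, "", 3L)
    start <- suppressWarnings(as.numeric(startc))
    end <- suppressWarnings(as.numeric(endc))
    badnum <- which(is.na(start) | is.na(end) |
                    start != floor(start) | end != floor(end))
    if (length(badnum))
        stop("BED format error at line ", lineno[badnum[1L]],
             ": non-integer coordinates '", startc[badnum[1L]], "', '",
             endc[badnum[1L]], "'")
    badiv <- which(start >= end | start < 0)
    if (length(badiv))
        stop("BED validation error at line ", lineno[badiv[1L]],
             ": required 0 <= start < end, got [", start[badiv[1L]], ", ",
             end[badiv[1L]], ")")
    id <- ifelse(ncols >= 4L, vapply(parts, function(p) p[4L], ""),
                 sprintf("%s:%d-%d", chrom, as.integer(start),
                         as.integer(end)))
    if (anyDuplicated(id))
        stop("BED validation error: duplicated region id '",
             id[duplicated(id)][1L], "'")
    gr <- GenomicRanges::GRanges(chrom,
                                 IRanges::IRanges(start + 1L, end), id = id)
    names(gr) <- id
    gr
}

#' Write a GRanges as BED
#'
#' Inverse of [readBed()]: writes 0-based half-open coordinates plus the
#' region names as column 4.
#'
#' @param gr a `GRanges`, ideally named.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
#' @importFrom GenomicRanges seqnames start end
writeBed <- function(gr, path) {
    id <- names(gr)
    if (is.null(id)) id <- sprintf("%s:%d-%d",
        as.character(GenomicRanges::seqnames(gr)),
        GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr))
    writeLines(sprintf("%s\t%d\t%d\t%s",
                       as.character(GenomicRanges::seqnames(gr)),
                       GenomicRanges::start(gr) - 1L,
                       GenomicRanges::end(gr), id), path)
    invisible(path)
}

#' Read a JASPAR-format position frequency matrix
#'
#' Parses the JASPAR 2016+ text format: a `>ID name` header followed by
#' four rows of bracketed counts labelled A, C, G, T (in any row order;
#' rows are mapped by their base label, not their position).
#'
#' @param path path to a JASPAR text file (first record is read).
#' @param pseudocount pseudocount stored on the returned matrix.
#' @return a [MotifMatrix-class].
#' @examples
#' f <- tempfile(fileext = ".jaspar")
#' writeLines(c(">MX0001 toy", "A [ 10 0 1 ]", "C [ 0 10 1 ]",
#'              "G [ 0 0 1 ]", "T [ 0 0 7 ]"), f)
#' readJaspar(f)
#' @export
readJaspar <- function(path, pseudocount = 0.8) {
    if (!file.exists(path)) stop("no such file: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L || !startsWith(lines[[1L]], ">"))
        stop("JASPAR format error: expected '>' header on first line")
    header <- sub("^>\\s*", "", lines[[1L]])
    name <- strsplit(header, "\\s+")[[1L]][1L]
    rows <- list()
    for (ln in lines[-1L]) {
        if (startsWith(ln, ">")) break
        m <- regmatches(ln, regexec("^\\s*([ACGT])\\s*\\[?\\s*([-0-9. \t]*)\\]?\\s*$",
                                    ln))[[1L]]
        if (length(m) == 0L)
            stop("JASPAR format error: unparseable row: ", ln)
        vals <- suppressWarnings(as.numeric(strsplit(trimws(m[3L]),
                                                     "\\s+")[[1L]]))
        if (any(is.na(vals)))
            stop("JASPAR format error: non-numeric counts in row: ", ln)
        rows[[m[2L]]] <- vals
    }
    miss <- setdiff(c("A", "C", "G", "T"), names(rows))
    if (length(miss))
        stop("JASPAR format error: missing row(s) for base(s): ",
             paste(miss, collapse = ", "))
    lens <- lengths(rows[c("A", "C", "G", "T")])
    if (length(unique(lens)) != 1L)
        stop("JASPAR format error: rows of unequal length (",
             paste(lens, collapse = ", "), ")")
    counts <- cbind(A = rows$A, C = rows$C, G = rows$G, T = rows$T)
    motifMatrix(name, counts, pseudocount = pseudocount)
}

#' Indicator PFM from a consensus string
#'
#' Builds a [MotifMatrix-class] that gives weight `hit` to the consensus
#' base at each position and 0 to the others; `N` positions get equal
#' counts on all four bases (a fully degenerate position).
#'
#' @param consensus a DNA string over A, C, G, T, N.
#' @param name motif name (defaults to the consensus itself).
#' @param hit count given to the consensus base, default 100.
#' @param pseudocount pseudocount stored on the matrix.
#' @return a [MotifMatrix-class].
#' @examples
#' consensusPFM("TCAAGGNCA")
#' @export
consensusPFM <- function(consensus, name = consensus, hit = 100,
                         pseudocount = 0.8) {
    stopIfNot1String(consensus, "consensus")
    code <- encodeDNA(consensus)
    L <- length(code)
    counts <- matrix(0, L, 4L, dimnames = list(NULL, DNA_BASES))
    for (i in seq_len(L)) {
        if (code[i] == 5L) counts[i, ] <- hit / 4
        else counts[i, code[i]] <- hit
    }
    motifMatrix(name, counts, pseudocount = pseudocount)
}

#' Read a tab-delimited table with a required-column schema
#'
#' Generic table reader behind the specific readers: tab-separated with a
#' header line (lines starting with `#` are skipped), required columns
#' checked by name and coerced to the requested types; extra columns are
#' kept as character.
#'
#' @param path path to the file.
#' @param required named character vector mapping required column names to
#'   types (`"character"`, `"numeric"`, `"integer"`); or a bare character
#'   vector of names (no coercion).
#' @return a data.frame.
#' @export
readTsv <- function(path, required = character()) {
    if (!file.exists(path)) stop("no such file: ", path)
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            comment.char = "#", check.names = FALSE,
                            colClasses = "character",
                            stringsAsFactors = FALSE)
    types <- if (is.null(names(required)))
        stats::setNames(rep(NA_character_, length(required)), required)
    else stats::setNames(unname(required), names(required))
    miss <- setdiff(names(types), colnames(df))
    if (length(miss))
        stop("table schema error: '", path, "' is missing required column(s): ",
             paste(miss, collapse = ", "))
    for (cn in names(types)) {
        ty <- types[[cn]]
        if (is.na(ty) || ty == "character") next
        val <- suppressWarnings(
            switch(ty, numeric = as.numeric(df[[cn]]),
                   integer = as.integer(df[[cn]]),
                   stop("unknown type: ", ty)))
        if (anyNA(val) && !anyNA(df[[cn]]))
            stop("table schema error: column '", cn, "' in '", path,
                 "' is not ", ty)
        df[[cn]] <- val
    }
    df
}

#' Read a region-by-sample counts table
#'
#' First column = region id, remaining columns = integer counts per sample.
#'
#' @param path path to the TSV.
#' @return an integer matrix with region-id rownames.
#' @export
readCountsTable <- function(path) {
    df <- readTsv(path)
    if (ncol(df) < 2L)
        stop("table schema error: counts table needs id + >=1 sample column")
    m <- as.matrix(df[, -1L, drop = FALSE])
    suppressWarnings(storage.mode(m) <- "double")
    if (anyNA(m)) stop("table schema error: non-numeric counts in ", path)
    rownames(m) <- df[[1L]]
    m
}

#' Read a gene annotation table
#'
#' Requires columns `gene_id`, `chrom`, `tss` (0-based bp) and `strand`
#' (`+`/`-`).
#'
#' @param path path to the TSV.
#' @return data.frame with typed columns; gene ids checked unique.
#' @export
readGeneTable <- function(path) {
    df <- readTsv(path, c(gene_id = "character", chrom = "character",
                          tss = "integer", strand = "character"))
    if (anyDuplicated(df$gene_id))
        stop("gene table validation error: duplicated gene_id")
    if (any(df$tss < 0)) stop("gene table validation error: negative tss")
    if (!all(df$strand %in% c("+", "-")))
        stop("gene table validation error: strand must be '+' or '-'")
    df
}

#' Read a differential-expression table
#'
#' Requires columns `gene`, `log2fc`, `fdr`; extra columns preserved.
#'
#' @param path path to the TSV.
#' @return data.frame.
#' @export
readDeTable <- function(path) {
    readTsv(path, c(gene = "character", log2fc = "numeric", fdr = "numeric"))
}

#' Write a data.frame as TSV with a commented provenance header
#'
#' All duoReg outputs go through this writer: a `#`-prefixed header naming
#' the package version and any parameters, then a tab-separated table.
#' Doubles are written with 6 significant digits so identical runs produce
#' byte-identical files.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param params named list of parameters recorded in the header.
#' @return `path`, invisibly.
#' @export
writeTsv <- function(df, path, params = list()) {
    ver <- as.character(utils::packageVersion("duoReg"))
    hdr <- c(sprintf("# duoReg %s", ver),
             vapply(names(params), function(k)
                 sprintf("# %s: %s", k, paste(format(params[[k]]),
                                              collapse = ",")), ""))
    out <- df
    for (cn in colnames(out))
        if (is.double(out[[cn]])) out[[cn]] <- formatNum(out[[cn]])
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    writeLines(paste(colnames(out), collapse = "\t"), con)
    if (nrow(out))
        writeLines(do.call(paste, c(lapply(out, as.character), sep = "\t")),
                   con)
    invisible(path)
}
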