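# Internal helpers shared across modules.

# Evaluate expr with a temporarily seeded RNG, restoring the caller's RNG
# state afterwards so library functions never perturb user-level randomness.
withSeed <- function(seed, expr) {
    if (!is.null(seed)) {
        has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
        old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
        on.exit({
            if (!is.null(old))
                assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv(),
                            inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        })
        set.seed(as.integer(seed))
    }
    force(expr)
}

# Deterministic per-stage seed derived from a top-level seed and a stage
# name; kept below 2^31 - 1.
deriveSeed <- function(seed, stage) {
    h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
    as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

DNA_BASES <- c("A", "C", "G", "T")

# Encode a DNA string as integer codes A=1 C=2 G=3 T=4, anything else
# (incl. N) = 5. Input may be a character scalar or an XString.
encodeDNA <- function(seq) {
    s <- toupper(as.character(seq))
    v <- strsplit(s, "", fixed = TRUE)[[1L]]
    code <- match(v, DNA_BASES)
    code[is.na(code)] <- 5L
    code
}

revCompCode <- function(code) {
    comp <- c(4L, 3L, 2L, 1L, 5L)
    rev(comp[code])
}

reverseComplement1 <- function(s) {
    chartr("ACGTNacgtn", "TGCANtgcan", paste(rev(strsplit(
        as.character(s), "", fixed = TRUE)[[1L]]), collapse = ""))
}

stopIfNot1String <- function(x, what) {
    if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x))
        stop(sprintf("'%s' must be a single non-empty string", what))
}

# fmt helper for TSV output: fixed 6 significant digits for doubles so
# repeated runs are byte-identical.
formatNum <- function(x) {
    ifelse(is.na(x), "NA",
           ifelse(x == floor(x) & abs(x) < 1e15 & !is.double(x),
                  format(x, scientific = FALSE),
                  formatC(x, digits = 6L, format = "g")))
}
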