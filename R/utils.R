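# internal helpers shared across modules

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. All package randomness flows through this so that
# operations are deterministic given their config seed and independent of
# surrounding code.
.withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
    expr
}

# Derive a child seed from a base seed and a counter, kept inside 32-bit
# integer range. Used to give each read / each replicate an independent,
# order-insensitive stream.
.childSeed <- function(seed, counter) {
    as.integer((as.numeric(seed) * 48271 + as.numeric(counter)) %%
        2147483647L)
}

.softmax <- function(z) {
    z <- z - max(z)
    e <- exp(z)
    e / sum(e)
}

.relu <- function(x) {
    x[x < 0] <- 0
    x
}

.assertDNA <- function(x, allowN = TRUE, what = "sequence") {
    ok <- if (allowN) grepl("^[ACGTN]*$", x) else grepl("^[ACGT]*$", x)
    if (!all(ok))
        stop(what, " contains characters outside ",
             if (allowN) "A/C/G/T/N" else "A/C/G/T", call. = FALSE)
    invisible(x)
}

.asCharacterReads <- function(x) {
    if (is(x, "ReadSet")) as.character(reads(x))
    else if (is(x, "DNAStringSet")) as.character(x)
    else if (is.character(x)) x
    else stop("expected a ReadSet, DNAStringSet or character vector")
}
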