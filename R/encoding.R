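#' The 21-symbol amino-acid alphabet used by the encoder
#'
#' The 20 standard amino acids plus a single combined symbol `*` covering
#' stop codons and ambiguous (N-containing) codons. Frameshift-induced
#' internal stops are frequent in error-containing long reads and are kept
#' as signal rather than truncating translation, so they need a channel of
#' their own; folding ambiguity into the same symbol keeps the encoding at
#' 21 dimensions.
#'
#' @return Character vector of 21 symbols in the fixed encoder order.
#' @examples
#' aminoAlphabet()
#' @export
aminoAlphabet <- function() {
    c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
      "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "*")
}

# symbol -> index lookup, built once at load time
.AA_INDEX <- NULL
.GC_MAP <- NULL  # codon -> alphabet index

.encInit <- function() {
    aa <- aminoAlphabet()
    idx <- seq_along(aa)
    names(idx) <- aa
    gc <- Biostrings::GENETIC_CODE
    map <- idx[gc]                       # stops ('*') map to index 21
    names(map) <- names(gc)
    assignInMyNamespace(".AA_INDEX", idx)
    assignInMyNamespace(".GC_MAP", map)
}

.aaIndex <- function() {
    if (is.null(.AA_INDEX)) .encInit()
    .AA_INDEX
}

.gcMap <- function() {
    if (is.null(.GC_MAP)) .encInit()
    .GC_MAP
}

#' Reverse complement of a DNA sequence
#'
#' Thin character-level wrapper around [Biostrings::reverseComplement()]
#' restricted to the A/C/G/T/N alphabet (N maps to N).
#'
#' @param dna A single DNA string.
#' @return The reverse-complemented string.
#' @examples
#' revComp("ATGC")  # "GCAT"
#' @export
revComp <- function(dna) {
    stopifnot(is.character(dna), length(dna) == 1L)
    .assertDNA(dna)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
}

#' Translate one reading frame of a DNA sequence
#'
#' Applies the standard genetic code to the codons starting at `offset`.
#' Trailing 1-2 bases are dropped. Stop codons emit `*` and translation
#' continues: reads are arbitrary fragments of coding sequence with
#' frameshift errors, so internal stops are expected and informative.
#' Codons containing `N` (or any non-ACGT base) also emit `*`.
#'
#' @param dna A single DNA string over A/C/G/T/N.
#' @param offset Reading-frame offset, 0, 1 or 2.
#' @return The peptide string over [aminoAlphabet()].
#' @examples
#' translateFrame("ATGGCC", 0)  # "MA"
#' translateFrame("ATGGCC", 1)  # "W"
#' translateFrame("ATGTAAATG", 0)  # "M*M"
#' @export
translateFrame <- function(dna, offset) {
    stopifnot(length(dna) == 1L, offset %in% 0:2)
    codes <- .frameCodesOne(dna, offset)
    paste(aminoAlphabet()[codes], collapse = "")
}

# integer codes (1..21) of one frame's translation
.frameCodesOne <- function(dna, offset) {
    L <- nchar(dna)
    n_codon <- (L - offset) %/% 3L
    if (n_codon <= 0L) return(integer(0))
    starts <- offset + 1L + 3L * (seq_len(n_codon) - 1L)
    codons <- substring(dna, starts, starts + 2L)
    codes <- unname(.gcMap()[codons])
    codes[is.na(codes)] <- 21L           # N-containing / unknown codons -> '*'
    codes
}

# the three forward-frame translations as integer code vectors
.frameCodes <- function(dna) {
    lapply(0:2, function(off) .frameCodesOne(dna, off))
}

# DNA integer codes 1..4 (A,C,G,T); N and others are dropped from encoding
# via 0 -> handled by one-hot builder as all-zero rows
.dnaCodes <- function(dna) {
    m <- c(A = 1L, C = 2L, G = 3L, T = 4L)
    v <- unname(m[strsplit(dna, "", fixed = TRUE)[[1]]])
    v[is.na(v)] <- 0L
    list(v)
}

#' 3-frame one-hot tensor encoding of a DNA read
#'
#' Translates `dna` in its three forward reading frames and stacks the
#' per-frame one-hot matrices into a single 3-channel tensor of shape
#' `3 x window x 21` (channel x codon position x alphabet symbol). Each
#' frame is truncated or zero-padded to `window` rows; padding rows are
#' all-zero, so pooled convolutional features are unaffected by pad length.
#'
#' @param dna A single DNA string over A/C/G/T/N.
#' @param window Number of codon positions in the tensor (default 1000,
#'   i.e. 3000 nt, the model's standard fragment size).
#' @return Numeric array of dim `c(3, window, 21)` with dimnames
#'   `(frame, position, symbol)`.
#' @examples
#' arr <- encode3Frame("ATGGCC", window = 4)
#' which(arr[1, 1, ] == 1)  # index of 'M'
#' @export
encode3Frame <- function(dna, window = 1000L) {
    stopifnot(window >= 1L)
    .assertDNA(dna)
    if (nchar(dna) == 0L)
        warning("empty DNA sequence: returning all-zero tensor")
    aa <- aminoAlphabet()
    arr <- array(0, dim = c(3L, window, 21L),
                 dimnames = list(frame = 0:2, position = NULL, symbol = aa))
    codes <- .frameCodes(dna)
    for (j in 1:3) {
        cj <- codes[[j]]
        n <- min(length(cj), window)
        if (n > 0L)
            arr[cbind(j, seq_len(n), cj[seq_len(n)])] <- 1
    }
    arr
}

#' Crop a read into model-window fragments
#'
#' Splits a read into consecutive non-overlapping fragments of at most
#' `window_nt` bases (the last fragment may be shorter); concatenating the
#' fragments reproduces the input. Long reads are classified fragment by
#' fragment and the per-read call aggregated afterwards.
#'
#' @param dna A single DNA string.
#' @param window_nt Fragment size in nucleotides; must be a multiple of 3.
#' @return Character vector of fragments.
#' @examples
#' nchar(cropRead(strrep("A", 7000), 3000))  # 3000 3000 1000
#' @export
cropRead <- function(dna, window_nt = 3000L) {
    stopifnot(length(dna) == 1L)
    if (window_nt < 3L || window_nt %% 3L != 0L)
        stop("window_nt must be a positive multiple of 3")
    L <- nchar(dna)
    if (L <= window_nt) return(dna)
    starts <- seq(1L, L, by = window_nt)
    substring(dna, starts, pmin(starts + window_nt - 1L, L))
}

# Decode an encoded tensor back to per-channel integer codes, checking the
# one-hot structure (padding = trailing all-zero rows).
.decodeTensor <- function(arr) {
    stopifnot(length(dim(arr)) == 3L, dim(arr)[1] == 3L, dim(arr)[3] == 21L)
    lapply(1:3, function(j) {
        m <- arr[j, , , drop = TRUE]
        if (is.null(dim(m))) m <- matrix(m, nrow = 1L)  # window == 1
        rs <- rowSums(m)
        n <- sum(rs > 0)
        if (n == 0L) return(integer(0))
        if (any(rs[seq_len(n)] != 1) || any(rs[-seq_len(n)] != 0))
            stop("tensor is not one-hot with trailing zero padding")
        max.col(m[seq_len(n), , drop = FALSE], ties.method = "first")
    })
}
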