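#' Specification of a synthetic protein-family benchmark
#'
#' Describes a set of homologous protein families in which each family
#' carries planted, fully conserved motifs (its discriminative signal and
#' the ground truth for filter interpretation) on a background that varies
#' between members at a fixed per-residue substitution rate. Stands in for
#' curated reference sets such as the GPCR sub-subfamilies at desk scale.
#'
#' @param n_families Number of families (>= 2).
#' @param protein_length Length of every member protein, in residues.
#' @param motifs_per_family Number of planted motifs per family.
#' @param motif_length Length of each motif, in residues.
#' @param within_family_substitution_rate Probability that a non-motif
#'   residue of a member differs from the family consensus. Default 0.5:
#'   diverse families whose only fully conserved signal is the motifs,
#'   the regime the classifier is designed for.
#' @param members_per_family Number of member proteins per family.
#' @param seed Integer seed; the whole family set is deterministic given it.
#' @return A validated list of class `familySpec`.
#' @examples
#' familySpec(n_families = 3, seed = 7)
#' @export
familySpec <- function(n_families = 5L, protein_length = 100L,
                       motifs_per_family = 2L, motif_length = 10L,
                       within_family_substitution_rate = 0.5,
                       members_per_family = 20L, seed = 1L) {
    spec <- list(n_families = as.integer(n_families),
                 protein_length = as.integer(protein_length),
                 motifs_per_family = as.integer(motifs_per_family),
                 motif_length = as.integer(motif_length),
                 within_family_substitution_rate =
                     within_family_substitution_rate,
                 members_per_family = as.integer(members_per_family),
                 seed = as.integer(seed))
    if (spec$n_families < 2L)
        stop("n_families must be >= 2")
    if (spec$motif_length * spec$motifs_per_family > spec$protein_length)
        stop("motif placement impossible: motif_length * motifs_per_family ",
             "exceeds protein_length")
    if (spec$within_family_substitution_rate < 0 ||
        spec$within_family_substitution_rate > 1)
        stop("within_family_substitution_rate must be in [0, 1]")
    if (spec$members_per_family < 1L)
        stop("members_per_family must be >= 1")
    class(spec) <- c("familySpec", "list")
    spec
}

# non-overlapping motif start positions on a length-L consensus
.placeMotifs <- function(L, n_motif, m_len) {
    for (attempt in 1:200) {
        starts <- sort(sample.int(L - m_len + 1L, n_motif))
        if (n_motif == 1L || all(diff(starts) >= m_len)) return(starts)
    }
    stop("could not place non-overlapping motifs; spec is inconsistent")
}

#' Generate labeled synthetic protein families
#'
#' For each family, draws a random consensus protein, plants the family's
#' motifs at non-overlapping positions, and derives member proteins that
#' carry the motifs exactly and differ from the consensus elsewhere at the
#' spec's substitution rate. Members are reverse-translated into coding
#' sequences with uniformly chosen synonymous codons. Deterministic given
#' `spec$seed`.
#'
#' @param spec A [familySpec()].
#' @return A [FamilyRef-class] object.
#' @examples
#' ref <- generateFamilies(familySpec(n_families = 2, seed = 3))
#' ref
#' @export
generateFamilies <- function(spec) {
    stopifnot(inherits(spec, "familySpec"))
    aa20 <- aminoAlphabet()[1:20]
    .withSeed(spec$seed, {
        fam_ids <- sprintf("fam%02d", seq_len(spec$n_families))
        motifs <- list()
        consensus <- character(spec$n_families)
        prot <- list(); fam_of <- list()
        for (f in seq_len(spec$n_families)) {
            cons <- sample(aa20, spec$protein_length, replace = TRUE)
            starts <- .placeMotifs(spec$protein_length,
                                   spec$motifs_per_family, spec$motif_length)
            mseq <- character(spec$motifs_per_family)
            in_motif <- rep(FALSE, spec$protein_length)
            for (k in seq_len(spec$motifs_per_family)) {
                pos <- starts[k]:(starts[k] + spec$motif_length - 1L)
                cons[pos] <- sample(aa20, spec$motif_length, replace = TRUE)
                mseq[k] <- paste(cons[pos], collapse = "")
                in_motif[pos] <- TRUE
            }
            motifs[[fam_ids[f]]] <- list(seqs = mseq, starts = starts)
            consensus[f] <- paste(cons, collapse = "")
            mem <- matrix(rep(cons, spec$members_per_family),
                          nrow = spec$protein_length)
            free <- which(!in_motif)
            for (m in seq_len(spec$members_per_family)) {
                mut <- free[stats::runif(length(free)) <
                            spec$within_family_substitution_rate]
                if (length(mut)) {
                    # substitute with a uniformly chosen *different* residue
                    cur <- match(mem[mut, m], aa20)
                    shift <- sample.int(19L, length(mut), replace = TRUE)
                    mem[mut, m] <- aa20[((cur - 1L + shift) %% 20L) + 1L]
                }
            }
            prot[[f]] <- apply(mem, 2, paste, collapse = "")
            fam_of[[f]] <- rep(fam_ids[f], spec$members_per_family)
        }
        proteins <- unlist(prot)
        family <- unlist(fam_of)
        names(proteins) <- sprintf("%s_m%02d", family,
            unlist(lapply(fam_of, seq_along)))
        cds <- vapply(seq_along(proteins), function(i)
            reverseTranslate(proteins[i],
                             seed = .childSeed(spec$seed, i)), "")
        names(cds) <- names(proteins)
        new("FamilyRef",
            proteins = Biostrings::AAStringSet(proteins),
            cds = Biostrings::DNAStringSet(cds),
            family = family,
            motifs = motifs,
            consensus = Biostrings::AAStringSet(
                stats::setNames(consensus, fam_ids)),
            spec = unclass(spec))
    })
}

#' Split reference families into training and test members
#'
#' Divides each family's members into a training and a test portion
#' *before* read simulation, so simulated training and test reads never
#' originate from the same reference sequence.
#'
#' @param ref A [FamilyRef-class].
#' @param train_fraction Fraction of members per family assigned to
#'   training (default 0.8).
#' @param seed Integer seed for the per-family shuffle.
#' @return List with `FamilyRef` elements `train` and `test`.
#' @export
splitReferences <- function(ref, train_fraction = 0.8, seed = 1L) {
    stopifnot(is(ref, "FamilyRef"), train_fraction > 0, train_fraction < 1)
    .withSeed(seed, {
        take <- logical(length(ref@proteins))
        for (f in unique(ref@family)) {
            idx <- which(ref@family == f)
            n_train <- max(1L, round(length(idx) * train_fraction))
            take[sample(idx, n_train)] <- TRUE
        }
        list(train = .subsetFamilyRef(ref, take),
             test = .subsetFamilyRef(ref, !take))
    })
}

.subsetFamilyRef <- function(ref, i) {
    new("FamilyRef", proteins = ref@proteins[i], cds = ref@cds[i],
        family = ref@family[i], motifs = ref@motifs,
        consensus = ref@consensus, spec = ref@spec)
}

#' Reverse-translate a protein into a coding sequence
#'
#' Chooses a synonymous codon uniformly at random per residue; translating
#' the result in frame 0 recovers the protein exactly.
#'
#' @param protein A single peptide string over the 20 standard amino acids.
#' @param seed Integer seed.
#' @return DNA string of length `3 * nchar(protein)`.
#' @examples
#' reverseTranslate("MW", seed = 1)  # "ATGTGG": sole codons
#' @export
reverseTranslate <- function(protein, seed = 1L) {
    stopifnot(is.character(protein), length(protein) == 1L)
    res <- strsplit(protein, "", fixed = TRUE)[[1]]
    tab <- .codonTable()
    if (any(!res %in% names(tab)))
        stop("unknown residue symbol(s): ",
             paste(unique(setdiff(res, names(tab))), collapse = ", "))
    .withSeed(seed, {
        paste(vapply(res, function(a) {
            cods <- tab[[a]]
            if (length(cods) == 1L) cods else sample(cods, 1L)
        }, "", USE.NAMES = FALSE), collapse = "")
    })
}

.CODON_TABLE <- NULL
.codonTable <- function() {
    if (is.null(.CODON_TABLE)) {
        gc <- Biostrings::GENETIC_CODE
        tab <- split(names(gc), gc)
        tab <- tab[names(tab) != "*"]    # proteins carry no stops
        assignInMyNamespace(".CODON_TABLE", tab)
    }
    .CODON_TABLE
}

#' Read-simulation configuration
#'
#' Parameters of the i.i.d. per-base error model used to emulate long-read
#' (PBSIM-style) sequencing: each base is hit independently with probability
#' `error_rate`; a hit is a substitution, a single-base insertion (after the
#' base) or a deletion, with probabilities `error_ratio`.
#'
#' @param error_rate Per-base error probability in `[0, 0.2]` (long-read
#'   instruments span roughly 1-15%).
#' @param error_ratio Length-3 non-negative vector
#'   (substitution, insertion, deletion) summing to 1. Default
#'   `c(10, 60, 30)/100`, the published PBSIM CLR default mix.
#' @param coverage Target fold coverage per reference sequence.
#' @param read_length_model Either `"full"` (every read spans its whole
#'   reference) or a numeric `c(mean, sd)` of a log-normal read-length
#'   distribution in nucleotides.
#' @param strand `"plus"` (all reads from the forward strand, the training
#'   convention) or `"both"` (half the reads reverse-complemented).
#' @param seed Integer seed.
#' @return A validated list of class `readSimConfig`.
#' @export
readSimConfig <- function(error_rate = 0.10,
                          error_ratio = c(10, 60, 30) / 100,
                          coverage = 80,
                          read_length_model = "full",
                          strand = c("plus", "both"),
                          seed = 1L) {
    strand <- match.arg(strand)
    if (error_rate < 0 || error_rate > 0.2)
        stop("error_rate must be in [0, 0.2]")
    if (length(error_ratio) != 3L || any(error_ratio < 0) ||
        abs(sum(error_ratio) - 1) > 1e-9)
        stop("error_ratio must be 3 non-negative values summing to 1")
    if (coverage <= 0) stop("coverage must be > 0")
    if (!(identical(read_length_model, "full") ||
          (is.numeric(read_length_model) && length(read_length_model) == 2L &&
           all(read_length_model > 0))))
        stop("read_length_model must be \"full\" or numeric c(mean, sd)")
    cfg <- list(error_rate = error_rate, error_ratio = error_ratio,
                coverage = coverage, read_length_model = read_length_model,
                strand = strand, seed = as.integer(seed))
    class(cfg) <- c("readSimConfig", "list")
    cfg
}

#' Inject sequencing errors into a DNA sequence
#'
#' Each base is hit independently with probability `config$error_rate`; the
#' hit type is drawn from `config$error_ratio`. Substitutions replace the
#' base with a uniformly chosen different base, insertions add one uniform
#' base after it, deletions remove it. The exact per-type counts are
#' attached as `attr(x, "error_counts")` so simulator calibration needs no
#' aligner.
#'
#' @param sequence A single DNA string over A/C/G/T.
#' @param config A [readSimConfig()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return The mutated DNA string with an `error_counts` attribute
#'   `c(sub, ins, del)`.
#' @export
injectErrors <- function(sequence, config, seed = config$seed) {
    stopifnot(inherits(config, "readSimConfig"))
    .assertDNA(sequence, allowN = FALSE)
    bases <- c("A", "C", "G", "T")
    s <- strsplit(sequence, "", fixed = TRUE)[[1]]
    n <- length(s)
    out <- .withSeed(seed, {
        if (n == 0L || config$error_rate == 0) {
            list(piece = s, counts = c(sub = 0L, ins = 0L, del = 0L))
        } else {
            hit <- which(stats::runif(n) < config$error_rate)
            piece <- s
            subs <- ins <- del <- integer(0)
            if (length(hit)) {
                type <- sample.int(3L, length(hit), replace = TRUE,
                                   prob = config$error_ratio)
                subs <- hit[type == 1L]
                if (length(subs)) {
                    # uniform over the three *other* bases
                    cur <- match(s[subs], bases)
                    shift <- sample.int(3L, length(subs), replace = TRUE)
                    piece[subs] <- bases[((cur - 1L + shift) %% 4L) + 1L]
                }
                ins <- hit[type == 2L]
                if (length(ins))
                    piece[ins] <- paste0(s[ins],
                        sample(bases, length(ins), replace = TRUE))
                del <- hit[type == 3L]
                if (length(del)) piece[del] <- ""
            }
            list(piece = piece,
                 counts = c(sub = length(subs), ins = length(ins),
                            del = length(del)))
        }
    })
    res <- paste(out$piece, collapse = "")
    attr(res, "error_counts") <- out$counts
    res
}

#' Simulate labeled long reads from reference coding sequences
#'
#' Draws reads per reference until the configured fold coverage is reached
#' (sum of read lengths / reference length >= coverage), with uniform start
#' positions under a partial-length model, then injects sequencing errors.
#' Labels are inherited from the references. With `strand = "both"`, half
#' the reads (to within one) are reverse-complemented. Deterministic given
#' `config$seed`.
#'
#' @param ref A [FamilyRef-class], or a named `DNAStringSet` /
#'   character vector of references with `labels` supplied.
#' @param config A [readSimConfig()].
#' @param labels Per-reference labels when `ref` is not a `FamilyRef`.
#' @return A [ReadSet-class] with per-read `ref`, `strand`, `start`, `end`,
#'   `frame_offset` and injected-error counts in its metadata.
#' @export
simulateReads <- function(ref, config, labels = NULL) {
    stopifnot(inherits(config, "readSimConfig"))
    if (is(ref, "FamilyRef")) {
        refs <- as.character(ref@cds)
        labels <- ref@family
    } else {
        refs <- .asCharacterReads(ref)
        if (is.null(labels)) stop("labels required for raw references")
    }
    if (length(refs) == 0L) stop("no reference sequences supplied")
    if (is.null(names(refs)))
        names(refs) <- sprintf("ref%03d", seq_along(refs))

    full <- identical(config$read_length_model, "full")
    if (!full) {
        m <- config$read_length_model[1]; sd <- config$read_length_model[2]
        sdlog <- sqrt(log(1 + (sd / m)^2))
        meanlog <- log(m) - sdlog^2 / 2
        if (m > min(nchar(refs)))
            warning("read length mean exceeds a reference length; ",
                    "reads clamped to full reference length")
    }

    counter <- 0L
    seqs <- character(0); lab <- character(0); rid <- character(0)
    strand <- character(0); st <- integer(0); en <- integer(0)
    frame_off <- integer(0)
    nsub <- integer(0); nins <- integer(0); ndel <- integer(0)

    for (r in seq_along(refs)) {
        refseq <- refs[r]; L <- nchar(refseq)
        target <- config$coverage * L
        got <- 0; i <- 0L
        while (got < target) {
            i <- i + 1L; counter <- counter + 1L
            sd_i <- .childSeed(config$seed, counter)
            draw <- .withSeed(sd_i, {
                len <- if (full) L else
                    max(30L, min(L, round(stats::rlnorm(1, meanlog, sdlog))))
                start <- if (len >= L) 1L else
                    sample.int(L - len + 1L, 1L)
                list(len = len, start = start)
            })
            frag <- substring(refseq, draw$start, draw$start + draw$len - 1L)
            mut <- injectErrors(frag, config,
                                seed = .childSeed(config$seed, counter + 500000L))
            cnt <- attr(mut, "error_counts")
            if (nchar(mut) == 0L) next   # pathological rates may erase a read
            seqs <- c(seqs, as.character(mut))
            lab <- c(lab, labels[r])
            rid <- c(rid, sprintf("%s_r%03d", names(refs)[r], i))
            strand <- c(strand, "+")
            st <- c(st, draw$start); en <- c(en, draw$start + draw$len - 1L)
            frame_off <- c(frame_off, (draw$start - 1L) %% 3L)
            nsub <- c(nsub, cnt["sub"]); nins <- c(nins, cnt["ins"])
            ndel <- c(ndel, cnt["del"])
            got <- got + draw$len
        }
    }

    if (config$strand == "both") {
        # exactly half (to within one) on the minus strand, seeded shuffle
        minus <- .withSeed(.childSeed(config$seed, 999999L),
            sample(seq_along(seqs), length(seqs) %/% 2L))
        for (k in minus) seqs[k] <- revComp(seqs[k])
        strand[minus] <- "-"
    }

    names(seqs) <- rid
    info <- DataFrame(label = lab, strand = strand, start = st, end = en,
                      frame_offset = frame_off,
                      n_sub = nsub, n_ins = nins, n_del = ndel,
                      ref = sub("_r[0-9]+$", "", rid))
    ReadSet(seqs, label = lab, labelNames = sort(unique(labels)), info = info)
}

#' Generate out-of-distribution ("outlier") reads
#'
#' Produces reads guaranteed to contain no trained domain, in one of two
#' modes. `"decoy"` (default) simulates reads from independently generated
#' decoy protein families, verified motif-disjoint from `avoid` by exact
#' substring absence -- biological-looking negatives, the right exposure set
#' for Outlier Exposure training. `"uniform"` emits uniform-random DNA.
#'
#' @param n Number of outlier reads (>= 0).
#' @param config A [readSimConfig()] controlling lengths and errors.
#' @param mode `"decoy"` or `"uniform"`.
#' @param avoid Optional [FamilyRef-class] whose motifs must not occur in
#'   the decoy families (checked on the error-free decoy proteins).
#' @param spec [familySpec()] template for the decoy families; its seed is
#'   replaced by one derived from `seed`.
#' @param seed Integer seed (defaults to `config$seed`).
#' @return A [ReadSet-class] with all labels `"OUTLIER"`.
#' @export
generateOutliers <- function(n, config = readSimConfig(),
                             mode = c("decoy", "uniform"),
                             avoid = NULL, spec = familySpec(),
                             seed = config$seed) {
    mode <- match.arg(mode)
    stopifnot(n >= 0)
    if (n == 0)
        return(ReadSet(Biostrings::DNAStringSet(),
                       label = character(0), labelNames = character(0)))
    if (mode == "uniform") {
        len0 <- if (identical(config$read_length_model, "full"))
            3L * spec$protein_length else config$read_length_model[1]
        seqs <- .withSeed(seed, vapply(seq_len(n), function(i)
            paste(sample(c("A", "C", "G", "T"), len0, replace = TRUE),
                  collapse = ""), ""))
        names(seqs) <- sprintf("outlier_u%04d", seq_len(n))
        return(ReadSet(seqs, label = OUTLIER_LABEL,
                       labelNames = character(0)))
    }
    # decoy mode: independent families, motif-disjoint from `avoid`
    decoy <- NULL
    for (try in 1:20) {
        dspec <- spec
        dspec$seed <- .childSeed(seed, 7000L + try)
        cand <- generateFamilies(dspec)
        if (is.null(avoid) || .motifDisjoint(cand, avoid)) {
            decoy <- cand; break
        }
    }
    if (is.null(decoy))
        stop("could not generate motif-disjoint decoy families")
    refs <- as.character(decoy@cds)
    reads <- character(n); rid <- character(n)
    for (i in seq_len(n)) {
        r <- ((i - 1L) %% length(refs)) + 1L
        mut <- injectErrors(refs[r], config,
                            seed = .childSeed(seed, 30000L + i))
        reads[i] <- as.character(mut)
        rid[i] <- sprintf("outlier_d%04d", i)
    }
    names(reads) <- rid
    ReadSet(reads, label = OUTLIER_LABEL, labelNames = character(0))
}

# TRUE when no planted motif of either reference occurs verbatim in the
# other's member proteins
.motifDisjoint <- function(a, b) {
    ma <- unlist(lapply(a@motifs, `[[`, "seqs"))
    mb <- unlist(lapply(b@motifs, `[[`, "seqs"))
    pa <- as.character(a@proteins); pb <- as.character(b@proteins)
    hitsIn <- function(motifs, prots)
        any(vapply(motifs, function(m)
            any(grepl(m, prots, fixed = TRUE)), TRUE))
    !(hitsIn(ma, pb) || hitsIn(mb, pa))
}

#' Concatenate ReadSets
#'
#' @param ... `ReadSet` objects.
#' @return A single [ReadSet-class]; `labelNames` is the sorted union.
#' @export
combineReadSets <- function(...) {
    parts <- list(...)
    stopifnot(all(vapply(parts, is, TRUE, "ReadSet")))
    seqs <- do.call(c, lapply(parts, reads))
    lab <- unlist(lapply(parts, readLabels))
    ln <- sort(unique(unlist(lapply(parts, labelNames))))
    ReadSet(seqs, label = lab, labelNames = ln)
}
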