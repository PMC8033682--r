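test_that("familySpec validates its invariants", {
    expect_error(familySpec(n_families = 1), "n_families")
    expect_error(familySpec(motifs_per_family = 6, motif_length = 20,
                            protein_length = 100), "motif placement")
    expect_error(familySpec(within_family_substitution_rate = 1.2), "rate")
})

test_that("zero substitution rate makes family members identical", {
    ref <- generateFamilies(familySpec(n_families = 2,
        within_family_substitution_rate = 0, members_per_family = 5,
        seed = 8))
    for (f in unique(referenceFamily(ref))) {
        p <- as.character(referenceProteins(ref))[referenceFamily(ref) == f]
        expect_equal(length(unique(p)), 1)
    }
})

test_that("motif positions are invariant; background mutates at the stated rate", {
    rate <- 0.3
    spec <- familySpec(n_families = 2, protein_length = 80,
                       motifs_per_family = 2, motif_length = 10,
                       within_family_substitution_rate = rate,
                       members_per_family = 500, seed = 13)
    ref <- generateFamilies(spec)
    for (f in names(familyMotifs(ref))) {
        idx <- referenceFamily(ref) == f
        mem <- do.call(rbind, strsplit(
            as.character(referenceProteins(ref))[idx], ""))
        cons <- strsplit(as.character(ref@consensus[[f]])[1], "")[[1]]
        mot <- familyMotifs(ref)[[f]]
        in_motif <- rep(FALSE, spec$protein_length)
        for (k in seq_along(mot$starts))
            in_motif[mot$starts[k]:(mot$starts[k] + spec$motif_length - 1)] <-
                TRUE
        # the 20 motif positions are invariant across members
        expect_true(all(apply(mem[, in_motif, drop = FALSE], 2,
                              function(col) length(unique(col)) == 1)))
        # non-motif mismatch fraction ~ Binomial(n, rate) expectation
        diff_frac <- mean(sweep(mem[, !in_motif], 2, cons[!in_motif], "!="))
        n_obs <- sum(idx) * sum(!in_motif)
        tol <- 3 * sqrt(rate * (1 - rate) / n_obs)
        expect_lt(abs(diff_frac - rate), tol)
    }
})

test_that("family generation is deterministic in the seed", {
    a <- generateFamilies(familySpec(n_families = 2, seed = 5))
    b <- generateFamilies(familySpec(n_families = 2, seed = 5))
    d <- generateFamilies(familySpec(n_families = 2, seed = 6))
    expect_identical(as.character(referenceProteins(a)),
                     as.character(referenceProteins(b)))
    expect_false(identical(as.character(referenceProteins(a)),
                           as.character(referenceProteins(d))))
    expect_false(identical(familyMotifs(a)$fam01$seqs,
                           familyMotifs(d)$fam01$seqs))
})

test_that("reverseTranslate round-trips through frame-0 translation", {
    expect_equal(reverseTranslate("M", seed = 1), "ATG")
    expect_equal(reverseTranslate("MW", seed = 1), "ATGTGG")
    expect_error(reverseTranslate("MBZ", seed = 1), "unknown residue")
    set.seed(55)
    aa20 <- aminoAlphabet()[1:20]
    for (i in 1:20) {
        p <- paste(sample(aa20, sample(5:60, 1), replace = TRUE),
                   collapse = "")
        cds <- reverseTranslate(p, seed = i)
        expect_equal(nchar(cds), 3 * nchar(p))
        expect_equal(translateFrame(cds, 0), p)
    }
})

test_that("injectErrors matches its binomial error model", {
    cfg0 <- readSimConfig(error_rate = 0, seed = 1)
    s <- randomDNA(500, seed = 2)
    expect_equal(as.character(injectErrors(s, cfg0)), s)

    long <- randomDNA(1e5, seed = 3)
    # substitution-only: Hamming count ~ Binomial(1e5, 0.1)
    cfg_sub <- readSimConfig(error_rate = 0.10, error_ratio = c(1, 0, 0),
                             seed = 4)
    mut <- injectErrors(long, cfg_sub)
    expect_equal(nchar(mut), nchar(long))
    mism <- sum(strsplit(as.character(mut), "")[[1]] !=
                strsplit(long, "")[[1]])
    expect_lt(abs(mism - 1e4), 3 * sqrt(1e5 * 0.1 * 0.9))
    expect_equal(unname(attr(mut, "error_counts")["sub"]), mism)

    # deletion-only: length ~ 0.95 L, alphabet unchanged
    cfg_del <- readSimConfig(error_rate = 0.05, error_ratio = c(0, 0, 1),
                             seed = 5)
    mut2 <- injectErrors(long, cfg_del)
    expect_lt(abs(nchar(mut2) - 0.95e5), 3 * sqrt(1e5 * 0.05 * 0.95))
    expect_true(grepl("^[ACGT]+$", mut2))
})

test_that("empirical per-type error rates calibrate within 3 binomial SD", {
    cfg <- readSimConfig(error_rate = 0.10,
                         error_ratio = c(10, 60, 30) / 100, seed = 6)
    long <- randomDNA(1e5, seed = 7)
    mut <- injectErrors(long, cfg)
    counts <- attr(mut, "error_counts")
    targets <- 0.10 * c(10, 60, 30) / 100
    for (k in 1:3) {
        expected <- 1e5 * targets[k]
        sd3 <- 3 * sqrt(1e5 * targets[k] * (1 - targets[k]))
        expect_lt(abs(counts[k] - expected), sd3)
    }
})

test_that("simulateReads meets coverage with inherited labels", {
    ref <- generateFamilies(familySpec(n_families = 2,
        members_per_family = 3, seed = 9))
    cfg <- readSimConfig(error_rate = 0, coverage = 10, seed = 10)
    rs <- simulateReads(ref, cfg)
    # full-length model: exactly 10 reads per reference
    expect_equal(length(rs), 10 * length(referenceCDS(ref)))
    # error-free reads are exact copies
    expect_true(all(as.character(reads(rs)) %in%
                    as.character(referenceCDS(ref))))
    # label integrity
    info <- readInfo(rs)
    m <- match(info$ref, names(referenceCDS(ref)))
    expect_equal(info$label, referenceFamily(ref)[m])
    # coverage conservation per reference
    for (r in unique(info$ref)) {
        tot <- sum(info$end[info$ref == r] - info$start[info$ref == r] + 1)
        L <- nchar(as.character(referenceCDS(ref)[[r]]))
        expect_gte(tot / L, 10)
        expect_lt(tot / L, 10 + 1 + 1e-9)  # full-length reads: < cov + 1
    }
})

test_that("simulateReads is deterministic and strand=both flips half", {
    ref <- generateFamilies(familySpec(n_families = 2,
        members_per_family = 3, seed = 9))
    cfg <- readSimConfig(error_rate = 0.05, coverage = 4,
                         strand = "both", seed = 11)
    a <- simulateReads(ref, cfg)
    b <- simulateReads(ref, cfg)
    expect_identical(as.character(reads(a)), as.character(reads(b)))
    st <- readInfo(a)$strand
    expect_lte(abs(sum(st == "-") - length(a) / 2), 1)
    # minus reads are the reverse complement of the plus-strand draw
    minus1 <- which(st == "-")[1]
    cfg_plus <- readSimConfig(error_rate = 0.05, coverage = 4,
                              strand = "plus", seed = 11)
    p <- simulateReads(ref, cfg_plus)
    expect_equal(unname(as.character(reads(a))[minus1]),
                 revComp(unname(as.character(reads(p))[minus1])))
})

test_that("partial-length reads have uniformish starts and honor coverage", {
    ref <- generateFamilies(familySpec(n_families = 2,
        members_per_family = 2, seed = 19))
    cfg <- readSimConfig(error_rate = 0, coverage = 8,
                         read_length_model = c(120, 40), seed = 20)
    rs <- simulateReads(ref, cfg)
    info <- readInfo(rs)
    L <- 300
    for (r in unique(info$ref)) {
        tot <- sum(info$end[info$ref == r] - info$start[info$ref == r] + 1)
        expect_gte(tot / L, 8)
    }
    expect_gt(length(unique(info$start)), 10)   # starts vary
    expect_true(all(info$frame_offset == (info$start - 1) %% 3))
})

test_that("generateOutliers: empty, motif-free, deterministic", {
    expect_equal(length(generateOutliers(0)), 0)
    spec <- familySpec(n_families = 2, seed = 14)
    ref <- generateFamilies(spec)
    cfg <- readSimConfig(error_rate = 0, coverage = 1, seed = 15)
    # uniform mode: no in-distribution motif occurs verbatim in any read
    u <- generateOutliers(300, cfg, mode = "uniform", spec = spec,
                          seed = 16)
    expect_true(all(readLabels(u) == OUTLIER_LABEL))
    motif_nts <- unlist(lapply(familyMotifs(ref), `[[`, "seqs"))
    hits <- vapply(motif_nts, function(m) {
        # scan the translated reads for the 10-mer peptide motif
        any(vapply(as.character(reads(u)), function(s)
            any(vapply(0:2, function(o)
                grepl(m, translateFrame(s, o), fixed = TRUE), TRUE)),
            TRUE))
    }, TRUE)
    expect_false(any(hits))
    # decoy mode: motif-disjoint families, deterministic
    d1 <- generateOutliers(50, cfg, mode = "decoy", avoid = ref,
                           spec = spec, seed = 17)
    d2 <- generateOutliers(50, cfg, mode = "decoy", avoid = ref,
                           spec = spec, seed = 17)
    expect_identical(as.character(reads(d1)), as.character(reads(d2)))
    expect_true(all(readLabels(d1) == OUTLIER_LABEL))
})

test_that("splitReferences divides members 80/20 before simulation", {
    ref <- generateFamilies(familySpec(n_families = 3, seed = 18))
    parts <- splitReferences(ref, seed = 18)
    expect_equal(length(referenceCDS(parts$train)), 3 * 16)
    expect_equal(length(referenceCDS(parts$test)), 3 * 4)
    expect_length(intersect(names(referenceCDS(parts$train)),
                            names(referenceCDS(parts$test))), 0)
})
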