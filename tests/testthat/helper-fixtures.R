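# Shared fixtures and independent oracles. Expensive objects (trained
# models) are built once per test run and memoized here.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
    if (!exists(key, envir = .fixtures))
        assign(key, force(expr), envir = .fixtures)
    get(key, envir = .fixtures)
}

# random DNA string
randomDNA <- function(n, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# --- independent oracles ---------------------------------------------------

# naive triple-loop multi-channel convolution (the Eq-style definition,
# computed window by window, channel by channel, symbol by symbol)
naiveConvFeature <- function(arr, filters, bias) {
    h <- nrow(filters[[1]])
    n <- dim(arr)[2]
    out <- numeric(n - h + 1L)
    for (i in seq_len(n - h + 1L)) {
        acc <- bias
        for (j in 1:3)
            for (k in seq_len(h))
                for (sym in 1:21)
                    acc <- acc + filters[[j]][k, sym] * arr[j, i + k - 1L, sym]
        out[i] <- max(0, acc)
    }
    out
}

# exhaustive threshold sweep over every observed score plus sentinels;
# returns the best achievable F1 (in-distribution detection, accept = s >= t)
bruteBestF1 <- function(scores_in, correct, scores_out) {
    cand <- unique(c(0, sort(unique(c(scores_in, scores_out))), 1))
    best <- 0
    for (t in cand) {
        acc_in <- scores_in >= t
        acc_out <- scores_out >= t
        n_acc <- sum(acc_in) + sum(acc_out)
        p <- if (n_acc == 0) 1 else sum(acc_in) / n_acc
        r <- sum(acc_in & correct) / length(scores_in)
        f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
        if (f1 > best) best <- f1
    }
    best
}

# --- small shared fixtures -------------------------------------------------

# a tiny trained 2-class model on trivially separable families, for
# inference/evaluation plumbing tests (fast: small reads, few epochs)
tinyFit <- function() memo("tinyFit", {
    spec <- familySpec(n_families = 2, protein_length = 60,
                       motif_length = 8, members_per_family = 8,
                       seed = 401)
    ref <- generateFamilies(spec)
    rs <- simulateReads(ref, readSimConfig(error_rate = 0, coverage = 5,
                                           seed = 402))
    m <- initModel(deskCnnConfig(n_classes = 2, window = 80), seed = 403)
    fit <- trainModel(m, rs, config = trainConfig(
        epochs = 5, learning_rate = 2e-3, batch_size = 32, seed = 403))
    list(spec = spec, ref = ref, reads = rs, fit = fit)
})

# the sanity benchmark: 3 families with disjoint planted motifs, 200
# error-free full-length reads each (coverage 10 x 20 members)
sanityData <- function() memo("sanityData", {
    spec <- familySpec(n_families = 3, seed = 11)
    ref <- generateFamilies(spec)
    rs <- simulateReads(ref, readSimConfig(error_rate = 0, coverage = 10,
                                           seed = 3))
    list(spec = spec, ref = ref, reads = rs)
})

sanityFit <- function(seed = 1) memo(paste0("sanityFit", seed), {
    sd <- sanityData()
    m <- initModel(deskCnnConfig(n_classes = 3, window = 120), seed = seed)
    trainModel(m, sd$reads, config = trainConfig(
        epochs = 10, learning_rate = 2e-3, seed = seed))
})
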