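test_that("convFeature matches hand-built indicator-filter expectations", {
    arr <- encode3Frame("ATGGCC", window = 4)
    zero <- lapply(1:3, function(j) matrix(0, 2, 21))
    expect_equal(convFeature(arr, zero, 0), rep(0, 3))
    # h = 1 filter that fires on 'M' in channel 0: counts motif occurrences
    ind <- lapply(1:3, function(j) matrix(0, 1, 21))
    ind[[1]][1, match("M", aminoAlphabet())] <- 1
    expect_equal(convFeature(arr, ind, 0), c(1, 0, 0, 0))
    expect_error(convFeature(arr, lapply(1:3, function(j) matrix(0, 9, 21))),
                 "exceeds")
})

test_that("convFeature equals the naive triple-loop oracle", {
    set.seed(21)
    for (i in 1:20) {
        n <- sample(4:12, 1)
        h <- sample(1:3, 1)
        arr <- encode3Frame(randomDNA(3 * n), window = n)
        filters <- lapply(1:3, function(j)
            matrix(rnorm(h * 21), h, 21))
        b <- rnorm(1)
        expect_equal(convFeature(arr, filters, b),
                     naiveConvFeature(arr, filters, b), tolerance = 1e-6)
    }
})

test_that("initialization is seed-deterministic with the expected size", {
    cfg <- deskCnnConfig(n_classes = 3, window = 100)
    a <- initModel(cfg, seed = 1)
    b <- initModel(cfg, seed = 1)
    d <- initModel(cfg, seed = 2)
    expect_identical(modelParams(a), modelParams(b))
    expect_false(identical(modelParams(a)$W1, modelParams(d)$W1))
    # closed-form parameter count from the architecture
    F1 <- 16; F2 <- 16; sizes <- c(8, 12, 16); H <- 64; K <- 3
    expected <- (3 * 3 * 21) * F1 + F1 +
        sum(sizes * F1 * F2 + F2) +
        length(sizes) * F2 * H + H + H * K + K
    expect_equal(nParameters(a), expected)
    expect_lt(nParameters(initModel(cnnConfig(n_classes = 86), seed = 1)),
              1e7)
})

test_that("forward output is a probability simplex point", {
    m <- initModel(deskCnnConfig(n_classes = 4, window = 60), seed = 3)
    set.seed(31)
    for (i in 1:10) {
        p <- forwardProbs(m, randomDNA(sample(60:180, 1)))
        expect_equal(sum(p), 1, tolerance = 1e-9)
        expect_true(all(p >= 0))
        expect_length(p, 4)
    }
})

test_that("padding rows never change the forward output", {
    m <- initModel(deskCnnConfig(n_classes = 3, window = 60), seed = 4)
    dna <- randomDNA(120, seed = 41)
    arr_small <- encode3Frame(dna, window = 45)
    arr_big <- encode3Frame(dna, window = 60)   # 15 extra all-zero rows
    expect_equal(forwardProbs(m, arr_small), forwardProbs(m, arr_big))
    # and the tensor path agrees with the string path
    expect_equal(forwardProbs(m, arr_big), forwardProbs(m, dna))
})

test_that("eval-mode forward is deterministic despite dropout config", {
    m <- initModel(deskCnnConfig(n_classes = 3, window = 60,
                                 dropout = 0.5), seed = 5)
    dna <- randomDNA(150, seed = 51)
    expect_identical(forwardProbs(m, dna), forwardProbs(m, dna))
})

test_that("max-over-time pooling accepts any length above the filter span", {
    m <- initModel(deskCnnConfig(n_classes = 3, window = 200), seed = 6)
    for (L in c(60, 150, 400, 620)) {
        p <- forwardProbs(m, randomDNA(L, seed = L))
        expect_equal(sum(p), 1, tolerance = 1e-9)
    }
    # far below the smallest conv2 span -> NULL
    expect_null(forwardProbs(m, "ATGGCC"))
})

test_that("ablation variants run and keep the simplex contract", {
    dna <- randomDNA(300, seed = 61)
    for (v in c("dna_onehot", "three_branch")) {
        m <- initModel(deskCnnConfig(n_classes = 3, window = 110,
                                     variant = v), seed = 7)
        p <- forwardProbs(m, dna)
        expect_equal(sum(p), 1, tolerance = 1e-9)
        expect_length(p, 3)
    }
    # three-branch shares one single-channel filter bank
    m3 <- initModel(deskCnnConfig(n_classes = 3, window = 110,
                                  variant = "three_branch"), seed = 7)
    expect_equal(nrow(modelParams(m3)$W1), 3 * 21)
    # DNA variant consumes nucleotide one-hot with tripled conv1 span
    md <- initModel(deskCnnConfig(n_classes = 3, window = 110,
                                  variant = "dna_onehot"), seed = 7)
    expect_equal(nrow(modelParams(md)$W1), 9 * 4)
})

test_that("backprop matches finite-difference gradients", {
    ns <- asNamespace("domainCNN")
    cfg <- unclass(cnnConfig(n_filters1 = 4, filter_sizes2 = c(3, 5),
                             n_filters2 = 3, hidden_units = 6,
                             n_classes = 3, dropout = 0, window = 30))
    m <- initModel(structure(cfg, class = c("cnnConfig", "list")),
                   seed = 42)
    params <- modelParams(m)
    dna <- randomDNA(75, seed = 43)
    codes <- ns$.codesFor(cfg, dna)
    y <- 2L
    lossAt <- function(p)
        crossEntropyLoss(ns$.forwardCodes(p, cfg, codes)$probs, y)
    fw <- ns$.forwardCodes(params, cfg, codes, keep = TRUE)
    dlog <- fw$probs; dlog[y] <- dlog[y] - 1
    g <- ns$.backwardCodes(params, cfg, fw, dlog)
    eps <- 1e-6
    set.seed(44)
    blocks <- list(
        list(\(p) p$W1, \(p, v) { p$W1[] <- v; p }, g$W1),
        list(\(p) p$b1, \(p, v) { p$b1 <- v; p }, g$b1),
        list(\(p) p$W2[[1]], \(p, v) { p$W2[[1]][] <- v; p }, g$W2[[1]]),
        list(\(p) p$W2[[2]], \(p, v) { p$W2[[2]][] <- v; p }, g$W2[[2]]),
        list(\(p) p$b2[[2]], \(p, v) { p$b2[[2]] <- v; p }, g$b2[[2]]),
        list(\(p) p$Wh, \(p, v) { p$Wh[] <- v; p }, g$Wh),
        list(\(p) p$Wo, \(p, v) { p$Wo[] <- v; p }, g$Wo),
        list(\(p) p$bo, \(p, v) { p$bo <- v; p }, g$bo))
    for (blk in blocks) {
        v <- blk[[1]](params)
        for (i in sample(length(v), min(10, length(v)))) {
            v2 <- v; v2[i] <- v[i] + eps
            v3 <- v; v3[i] <- v[i] - eps
            num <- (lossAt(blk[[2]](params, v2)) -
                    lossAt(blk[[2]](params, v3))) / (2 * eps)
            expect_equal(blk[[3]][i], num, tolerance = 1e-4)
        }
    }
})
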