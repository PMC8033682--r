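test_that("classificationAccuracy counts top-1 matches", {
    calls <- c(r1 = "a", r2 = "a", r3 = "b", r4 = "b", r5 = "b",
               r6 = "c", r7 = "c", r8 = "a", r9 = "b", r10 = "c")
    truth <- c(r1 = "a", r2 = "a", r3 = "b", r4 = "b", r5 = "b",
               r6 = "c", r7 = "c", r8 = "b", r9 = "c", r10 = "c")
    expect_equal(classificationAccuracy(calls, truth), 0.8)
    expect_equal(classificationAccuracy(truth, truth), 1)
    expect_error(classificationAccuracy(calls[-1], truth), "ids")
    # random assignment over K classes scores ~ 1/K
    set.seed(111)
    n <- 6000; K <- 3
    ids <- sprintf("x%d", 1:n)
    t2 <- setNames(sample(letters[1:K], n, replace = TRUE), ids)
    c2 <- setNames(sample(letters[1:K], n, replace = TRUE), ids)
    expect_lt(abs(classificationAccuracy(c2, t2) - 1 / K),
              3 * sqrt((1 / K) * (1 - 1 / K) / n))
})

test_that("detectionMetrics matches hand-counted contingency values", {
    truth <- c(a1 = "a", a2 = "a", a3 = "a", b1 = "b", b2 = "b",
               o1 = "OUTLIER", o2 = "OUTLIER", o3 = "OUTLIER")
    calls <- c(a1 = "a", a2 = "b", a3 = "REJECT", b1 = "b", b2 = "b",
               o1 = "REJECT", o2 = "a", o3 = "REJECT")
    m <- detectionMetrics(calls, truth)
    # correct in-class calls: a1, b1, b2 of 5 in-class reads
    expect_equal(m$recall, 3 / 5)
    # labeled reads: a1, a2, b1, b2, o2 -> 4 in-class of 5 labeled
    expect_equal(m$precision, 4 / 5)
    expect_equal(m$micro_f1,
                 2 * (3 / 5) * (4 / 5) / (3 / 5 + 4 / 5),
                 tolerance = 1e-12)
    expect_equal(m$n, 8)
    expect_equal(sum(m$confusion), 8)
    pc <- m$per_class
    expect_equal(pc$recall[pc$class == "a"], 1 / 3)
    expect_equal(pc$precision[pc$class == "b"], 2 / 3)
})

test_that("perfect detection yields unit metrics", {
    truth <- c(r1 = "a", r2 = "b", r3 = "OUTLIER")
    calls <- c(r1 = "a", r2 = "b", r3 = "REJECT")
    m <- detectionMetrics(calls, truth)
    expect_equal(m$recall, 1)
    expect_equal(m$precision, 1)
    expect_equal(m$micro_f1, 1)
})

test_that("micro-F1 identity and the accept-all closed form hold exactly", {
    # 10% in-distribution mixture, accept-all with perfect classification
    n_in <- 30; n_out <- 270
    ids <- sprintf("r%03d", seq_len(n_in + n_out))
    truth <- setNames(c(rep(c("a", "b", "c"), length.out = n_in),
                        rep("OUTLIER", n_out)), ids)
    calls <- truth
    calls[truth == "OUTLIER"] <- rep(c("a", "b", "c"),
                                     length.out = n_out)  # accept-all
    m <- detectionMetrics(calls, truth)
    expect_equal(m$recall, 1)
    expect_equal(m$precision, 0.1)
    expect_equal(m$micro_f1, 2 * 0.1 / 1.1, tolerance = 1e-12)
    expect_equal(m$micro_f1,
                 2 * m$precision * m$recall / (m$precision + m$recall),
                 tolerance = 1e-9)
})

test_that("frame-order experiment reports six accuracies with delta >= 0", {
    tf <- tinyFit()
    fo <- frameOrderExperiment(tf$fit$model, tf$reads[1:30])
    expect_length(fo$accuracy, 6)
    expect_gte(fo$delta, 0)
    expect_equal(fo$delta, max(fo$accuracy) - min(fo$accuracy))
    # identity order equals plain classification accuracy
    plain <- classificationAccuracy(
        predictReads(tf$fit$model, tf$reads[1:30]), tf$reads[1:30])
    expect_equal(unname(fo$accuracy["123"]), plain)
})

test_that("extractActivatedFragments obeys its window and activation contracts", {
    tf <- tinyFit()
    expect_equal(nrow(extractActivatedFragments(tf$fit$model,
                                                tf$reads[1:5], top_k = 0)),
                 0)
    fr <- extractActivatedFragments(tf$fit$model, tf$reads[1:30],
                                    top_k = 2)
    expect_gt(nrow(fr), 0)
    expect_true(all(fr$activation > 0))
    expect_true(all(fr$channel %in% 1:3))
    # receptive span of a size-s filter is s + h1 - 1 codons
    sizes <- as.integer(sub("^size(\\d+)_.*", "\\1", fr$filter_id))
    expect_true(all(nchar(fr$fragment) <= sizes + 3 - 1))
    expect_true(all(grepl("^[ACDEFGHIKLMNPQRSTVWY*]+$", fr$fragment)))
})

test_that("untrained filters find no conserved columns in random reads", {
    m <- initModel(deskCnnConfig(n_classes = 3, window = 120), seed = 5)
    m@trained <- TRUE
    m@labelNames <- c("a", "b", "c")
    ro <- generateOutliers(100, readSimConfig(error_rate = 0, coverage = 1,
                                              seed = 6),
                           mode = "uniform", seed = 6)
    fr <- extractActivatedFragments(m, ro, top_k = 1)
    for (ch in 1:3) {
        sub <- fr[fr$channel == ch, ]
        if (nrow(sub) < 50) next
        cons <- fragmentConsensus(sub$fragment)
        expect_lt(max(cons$support), 0.6)
    }
})

test_that("longestCommonSubstring finds contiguous overlaps", {
    expect_equal(longestCommonSubstring("ABCDEF", "ZZCDEZZ"), 3)
    expect_equal(longestCommonSubstring("AAAA", "TTTT"), 0)
    expect_equal(longestCommonSubstring("", "ABC"), 0)
    expect_equal(longestCommonSubstring("PGKWASTENV", "XXPGKWASXX"), 6)
})

test_that("fragmentConsensus reports modal residues with support", {
    fc <- fragmentConsensus(c("MAD", "MAE", "MAD", "MKD"))
    expect_equal(fc$consensus, "MAD")
    expect_equal(fc$support, c(1, 0.75, 0.75))
})
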