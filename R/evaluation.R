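# coerce predictReads()/detect() output or a named vector to a named
# character vector of calls
.asCallVector <- function(calls, column = NULL) {
    if (is.data.frame(calls)) {
        col <- column %||% if ("call" %in% names(calls)) "call" else "label"
        stats::setNames(as.character(calls[[col]]), calls$read_id)
    } else calls
}

.asTruthVector <- function(truth) {
    if (is(truth, "ReadSet"))
        stats::setNames(readLabels(truth), names(reads(truth)))
    else truth
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Top-1 classification accuracy
#'
#' @param calls Named character vector of predicted labels, or the
#'   `data.frame` returned by [predictReads()] / [detect()].
#' @param truth Named character vector of true labels, or a
#'   [ReadSet-class].
#' @return Fraction of reads whose call equals the truth.
#' @export
classificationAccuracy <- function(calls, truth) {
    calls <- .asCallVector(calls)
    truth <- .asTruthVector(truth)
    if (!setequal(names(calls), names(truth)))
        stop("call and truth read ids do not match")
    truth <- truth[names(calls)]
    mean(calls == truth)
}

#' Detection metrics: recall, precision, micro-F1
#'
#' Metrics for open-set domain detection over a read set mixing
#' in-distribution families with outliers. Recall is the fraction of
#' in-distribution reads that received their correct family label;
#' precision is the fraction of reads given *any* family label that are
#' truly in-distribution; micro-F1 is their harmonic mean. Per-class
#' recall/precision/F1 and the full confusion table are included.
#'
#' @param calls Calls as in [classificationAccuracy()]; rejected reads
#'   carry the label `"REJECT"`.
#' @param truth Truth as in [classificationAccuracy()]; outlier reads
#'   carry the label `"OUTLIER"`.
#' @return A list of class `metricReport`: `recall`, `precision`,
#'   `micro_f1`, `accuracy` (among in-distribution reads), `per_class`
#'   data.frame, `confusion` table, `n`.
#' @export
detectionMetrics <- function(calls, truth) {
    calls <- .asCallVector(calls)
    truth <- .asTruthVector(truth)
    if (!setequal(names(calls), names(truth)))
        stop("call and truth read ids do not match")
    truth <- truth[names(calls)]
    is_in <- truth != OUTLIER_LABEL
    labeled <- calls != REJECT_LABEL
    recall <- sum(is_in & labeled & calls == truth) / sum(is_in)
    precision <- if (sum(labeled) == 0) 1 else
        sum(labeled & is_in) / sum(labeled)
    micro_f1 <- if (precision + recall == 0) 0 else
        2 * precision * recall / (precision + recall)
    fams <- sort(unique(truth[is_in]))
    per_class <- do.call(rbind, lapply(fams, function(f) {
        tp <- sum(calls == f & truth == f)
        rec <- tp / sum(truth == f)
        prec <- if (sum(calls == f) == 0) NA_real_ else tp / sum(calls == f)
        f1 <- if (is.na(prec) || prec + rec == 0) 0 else
            2 * prec * rec / (prec + rec)
        data.frame(class = f, recall = rec, precision = prec, f1 = f1)
    }))
    out <- list(recall = recall, precision = precision, micro_f1 = micro_f1,
                accuracy = mean((calls == truth)[is_in]),
                per_class = per_class,
                confusion = table(truth = truth, call = calls),
                n = length(calls))
    class(out) <- c("metricReport", "list")
    out
}

#' @export
print.metricReport <- function(x, ...) {
    cat(sprintf(
        "metricReport (n = %d): recall %.4f, precision %.4f, micro-F1 %.4f\n",
        x$n, x$recall, x$precision, x$micro_f1))
    invisible(x)
}

#' Frame-order permutation experiment
#'
#' Re-runs classification with each of the six permutations of the three
#' translation channels applied to the test reads (the trained model is
#' untouched) and reports accuracy per order plus the max-minus-min
#' accuracy spread. A model trained on reads whose start positions vary
#' sees every frame phase in every channel and should be nearly
#' order-insensitive.
#'
#' @param model A trained [DomainCNN-class].
#' @param x Test reads ([ReadSet-class] recommended; its labels are the
#'   default truth).
#' @param truth Optional named truth vector.
#' @param ... Passed to [predictReads()].
#' @return A list of class `frameOrderResult`: `accuracy` (named vector
#'   over the 6 orders) and `delta` (max - min).
#' @export
frameOrderExperiment <- function(model, x, truth = NULL, ...) {
    truth <- .asTruthVector(truth %||% x)
    perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                  c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
    acc <- vapply(perms, function(p) {
        calls <- predictReads(model, x, frame_order = p, ...)
        classificationAccuracy(calls, truth)
    }, 0)
    names(acc) <- vapply(perms, paste, "", collapse = "")
    out <- list(accuracy = acc, delta = max(acc) - min(acc))
    class(out) <- c("frameOrderResult", "list")
    out
}

#' @export
print.frameOrderResult <- function(x, ...) {
    cat("frameOrderResult: accuracy per channel order\n")
    print(round(x$accuracy, 4))
    cat(sprintf("  delta (max - min) = %.4f\n", x$delta))
    invisible(x)
}

#' Extract the peptide fragments that activate convolutional filters
#'
#' Ranks the second-layer filters by how often they win the max-over-time
#' pool across the given reads (pool-winner frequency: the filter whose
#' pooled activation is the largest of all filters for a read scores one
#' win). For each of the `top_k` filters it emits, per read and per frame
#' channel, the peptide window under the filter's receptive field at its
#' argmax position, together with the activation value. Stacking these
#' windows column-wise recovers the conserved (planted) motif the filter
#' has learned.
#'
#' @param model A trained [DomainCNN-class] (`three_frame` variant).
#' @param x Reads, typically all test reads of one family.
#' @param top_k How many top-ranked filters to extract (0 gives an empty
#'   result).
#' @param mode `"all"` (default): fragments from every read; `"winners"`:
#'   only from reads where the filter won the pool.
#' @return A `data.frame` of class `activatedFragments`: `filter_id`
#'   (`size<h>_f<j>`), `read_id`, `channel` (frame 1-3), `fragment`
#'   (peptide window), `activation`, `position`. Only fragments with
#'   positive activation are emitted.
#' @export
extractActivatedFragments <- function(model, x, top_k = 1L,
                                      mode = c("all", "winners")) {
    mode <- match.arg(mode)
    stopifnot(is(model, "DomainCNN"), isTRUE(model@trained))
    cfg <- model@config
    if (cfg$variant == "dna_onehot")
        stop("fragment extraction is defined for the 3-frame variants")
    if (top_k == 0L) {
        out <- data.frame(filter_id = character(0), read_id = character(0),
                          channel = integer(0), fragment = character(0),
                          activation = numeric(0), position = integer(0))
        class(out) <- c("activatedFragments", "data.frame")
        return(out)
    }
    g <- .geom(cfg)
    F2 <- cfg$n_filters2
    sizes <- rep(g$s2, each = F2)
    fids <- sprintf("size%d_f%d", sizes, rep(seq_len(F2), length(g$s2)))
    seqs <- .asCharacterReads(x)
    if (is.null(names(seqs)))
        names(seqs) <- sprintf("read%05d", seq_along(seqs))
    fw_all <- lapply(seqs, function(s)
        .forwardCodes(model@params, cfg, .codesFor(cfg, s), keep = TRUE))
    ok <- !vapply(fw_all, is.null, TRUE)
    fw_all <- fw_all[ok]; seqs <- seqs[ok]
    # pool-winner frequency over the (first-branch) pooled features
    winner <- vapply(fw_all, function(fw)
        which.max(fw$branches[[1]]$pooled), 1L)
    freq <- tabulate(winner, nbins = length(fids))
    top <- order(freq, decreasing = TRUE)[seq_len(min(top_k, length(fids)))]
    # receptive-field span of a size-s second-layer filter, in codons
    span <- function(s) s + g$h1 - 1L + (if (isTRUE(cfg$extra_layer)) 2L else 0L)
    rows <- list()
    for (fid in top) {
        s <- sizes[fid]
        use <- if (mode == "winners") which(winner == fid) else
            seq_along(fw_all)
        for (ri in use) {
            bo <- fw_all[[ri]]$branches[[1]]
            a <- bo$argmax[fid]; act <- bo$pooled[fid]
            if (is.na(a) || act <= 0) next
            peps <- lapply(0:2, function(off)
                translateFrame(seqs[ri], off))
            for (ch in 1:3) {
                frag <- substring(peps[[ch]], a, a + span(s) - 1L)
                if (nchar(frag) == 0L) next
                rows[[length(rows) + 1L]] <- data.frame(
                    filter_id = fids[fid], read_id = names(seqs)[ri],
                    channel = ch, fragment = frag, activation = act,
                    position = a)
            }
        }
    }
    out <- if (length(rows)) do.call(rbind, rows) else
        data.frame(filter_id = character(0), read_id = character(0),
                   channel = integer(0), fragment = character(0),
                   activation = numeric(0), position = integer(0))
    class(out) <- c("activatedFragments", "data.frame")
    out
}

#' Per-column consensus of a stack of peptide fragments
#'
#' @param fragments Character vector of equal-offset peptide windows (e.g.
#'   one filter/channel slice of [extractActivatedFragments()] output).
#' @return A list: `consensus` (modal residue string over the shortest
#'   common length) and `support` (per-column frequency of the modal
#'   residue).
#' @export
fragmentConsensus <- function(fragments) {
    stopifnot(length(fragments) > 0)
    L <- min(nchar(fragments))
    m <- do.call(rbind, strsplit(substr(fragments, 1L, L), ""))
    cons <- character(L); supp <- numeric(L)
    for (j in seq_len(L)) {
        tab <- sort(table(m[, j]), decreasing = TRUE)
        cons[j] <- names(tab)[1]
        supp[j] <- tab[1] / nrow(m)
    }
    list(consensus = paste(cons, collapse = ""), support = supp)
}

#' Length of the longest common substring of two strings
#'
#' Used to score how much of a planted motif a filter consensus recovers.
#'
#' @param a,b Character strings.
#' @return Integer length of the longest contiguous shared substring.
#' @export
longestCommonSubstring <- function(a, b) {
    x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
    if (!length(x) || !length(y)) return(0L)
    prev <- integer(length(y)); best <- 0L
    for (i in seq_along(x)) {
        cur <- integer(length(y))
        for (j in seq_along(y)) {
            if (x[i] == y[j]) {
                cur[j] <- (if (j > 1L) prev[j - 1L] else 0L) + 1L
                if (cur[j] > best) best <- cur[j]
            }
        }
        prev <- cur
    }
    best
}

#' Write activated fragments as FASTA
#'
#' Headers carry `filter_id|read_id|channel|activation`, ready for
#' external sequence-logo tools.
#'
#' @param fragments Output of [extractActivatedFragments()].
#' @param file Output path.
#' @return Invisibly, the path.
#' @export
writeFragments <- function(fragments, file) {
    seqs <- Biostrings::AAStringSet(gsub("\\*", "X", fragments$fragment))
    names(seqs) <- sprintf("%s|%s|frame%d|%.4f", fragments$filter_id,
                           fragments$read_id, fragments$channel,
                           fragments$activation)
    Biostrings::writeXStringSet(seqs, file)
    invisible(file)
}
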