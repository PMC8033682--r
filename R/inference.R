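#' Classify reads: six frames, fragment-aware
#'
#' Each read is cropped into fragments of at most `window_nt` bases; every
#' fragment is encoded on both the given strand and its reverse complement
#' (together covering all six reading frames) and pushed through the
#' network in evaluation mode. The read's softmax vector is the one with
#' the largest maximum probability across all (fragment, strand) passes --
#' a read is called as containing a domain as soon as one of its passes
#' does. Reads shorter than the smallest filter span get status
#' `"too_short"` and are never accepted.
#'
#' @param model A trained [DomainCNN-class].
#' @param x A [ReadSet-class], `DNAStringSet`, or named character vector.
#' @param window_nt Fragment size in nt; defaults to the model's window.
#' @param threshold Optional max-softmax acceptance threshold in `[0, 1]`
#'   (see [calibrateThreshold()]); when supplied, the `accepted` column is
#'   `score >= threshold`.
#' @param frame_order Permutation of `1:3` applied to the three translation
#'   channels at encoding time (frame-order experiments; default identity).
#' @return A `data.frame` with one row per read: `read_id`, `label`,
#'   `score` (max softmax), `strand`, `fragment`, `status`, `accepted`.
#'   The full softmax matrix of the winning passes is attached as
#'   `attr(, "softmax")`.
#' @export
predictReads <- function(model, x, window_nt = NULL, threshold = NULL,
                         frame_order = 1:3) {
    stopifnot(is(model, "DomainCNN"), isTRUE(model@trained))
    stopifnot(identical(sort(frame_order), 1:3) ||
              identical(sort(as.integer(frame_order)), 1:3))
    cfg <- model@config
    if (is.null(window_nt)) window_nt <- 3L * cfg$window
    seqs <- .asCharacterReads(x)
    if (is.null(names(seqs)))
        names(seqs) <- sprintf("read%05d", seq_along(seqs))
    K <- cfg$n_classes
    n <- length(seqs)
    lab <- character(n); sc <- numeric(n); strnd <- character(n)
    frag_i <- integer(n); status <- character(n)
    soft <- matrix(NA_real_, n, K)
    ln <- model@labelNames
    colnames(soft) <- ln
    for (r in seq_len(n)) {
        frags <- cropRead(seqs[r], window_nt)
        best <- NULL
        for (fi in seq_along(frags)) {
            for (st in c("+", "-")) {
                fseq <- if (st == "+") frags[fi] else revComp(frags[fi])
                codes <- .codesFor(cfg, fseq)
                if (cfg$variant != "dna_onehot")
                    codes <- codes[frame_order]
                fw <- .forwardCodes(model@params, cfg, codes)
                if (is.null(fw)) next
                m <- max(fw$probs)
                if (is.null(best) || m > best$m)
                    best <- list(m = m, p = fw$probs, st = st, fi = fi)
            }
        }
        if (is.null(best)) {
            lab[r] <- NA_character_; sc[r] <- NA_real_
            strnd[r] <- NA_character_; frag_i[r] <- NA_integer_
            status[r] <- "too_short"
        } else {
            k <- which.max(best$p)
            lab[r] <- if (length(ln)) ln[k] else as.character(k)
            sc[r] <- best$m; strnd[r] <- best$st; frag_i[r] <- best$fi
            status[r] <- "ok"
            soft[r, ] <- best$p
        }
    }
    accepted <- if (is.null(threshold)) rep(NA, n) else
        !is.na(sc) & sc >= threshold
    out <- data.frame(read_id = names(seqs), label = lab, score = sc,
                      strand = strnd, fragment = frag_i, status = status,
                      accepted = accepted, stringsAsFactors = FALSE)
    attr(out, "softmax") <- soft
    out
}

#' Calibrate the max-softmax acceptance threshold
#'
#' Sweeps candidate thresholds (midpoints between consecutive distinct
#' observed scores, plus sentinels 0 and 1) over a holdout containing both
#' in-distribution and out-of-distribution scores, and returns the
#' threshold maximizing the F1 score of in-distribution detection,
#' tie-broken toward the smallest threshold. A read is "accepted" when its
#' score is `>= t`. Recall is the fraction of in-distribution reads that
#' are accepted *and* correctly classified; precision is the fraction of
#' accepted reads that are in-distribution; when nothing is accepted,
#' precision is defined as 1 so the sweep is total.
#'
#' @param scores_in `data.frame` with columns `score` and logical
#'   `correct` for the in-distribution holdout reads, or a numeric vector
#'   with `correct` supplied separately.
#' @param scores_out Numeric vector of out-of-distribution scores.
#' @param correct Logical vector when `scores_in` is numeric.
#' @return A list of class `calibrationResult`: `threshold`, `f1`,
#'   `precision`, `recall`.
#' @export
calibrateThreshold <- function(scores_in, scores_out, correct = NULL) {
    if (is.data.frame(scores_in)) {
        correct <- scores_in$correct
        scores_in <- scores_in$score
    }
    stopifnot(length(scores_in) > 0, length(scores_out) > 0,
              length(correct) == length(scores_in))
    cand <- sort(unique(c(scores_in, scores_out)))
    cand <- unique(c(0, if (length(cand) > 1)
        (cand[-1] + cand[-length(cand)]) / 2, 1))
    best <- NULL
    for (t in cand) {
        m <- .detectionF1(scores_in, correct, scores_out, t)
        if (is.null(best) || m$f1 > best$f1 + 1e-15)
            best <- c(list(threshold = t), m)
    }
    class(best) <- c("calibrationResult", "list")
    best
}

# precision/recall/F1 of in-distribution detection at threshold t
.detectionF1 <- function(scores_in, correct, scores_out, t) {
    acc_in <- scores_in >= t
    acc_out <- scores_out >= t
    n_acc <- sum(acc_in) + sum(acc_out)
    precision <- if (n_acc == 0) 1 else sum(acc_in) / n_acc
    recall <- sum(acc_in & correct) / length(scores_in)
    f1 <- if (precision + recall == 0) 0 else
        2 * precision * recall / (precision + recall)
    list(f1 = f1, precision = precision, recall = recall)
}

#' @export
print.calibrationResult <- function(x, ...) {
    cat(sprintf(
        "calibrationResult: t* = %.4f  F1 = %.4f  (P = %.4f, R = %.4f)\n",
        x$threshold, x$f1, x$precision, x$recall))
    invisible(x)
}

#' Detect trained domains in reads, rejecting outliers
#'
#' Runs [predictReads()] and replaces the label of every read whose
#' max-softmax score falls below `threshold` (or that is too short to
#' classify) with `"REJECT"`.
#'
#' @param model A trained [DomainCNN-class].
#' @param x Reads as in [predictReads()].
#' @param threshold Calibrated acceptance threshold in `[0, 1]`.
#' @param file Optional path: write the calls as TSV.
#' @param ... Passed on to [predictReads()].
#' @return The [predictReads()] `data.frame` with a `call` column holding
#'   the final family-or-`REJECT` decision.
#' @export
detect <- function(model, x, threshold, file = NULL, ...) {
    stopifnot(threshold >= 0)
    out <- predictReads(model, x, threshold = threshold, ...)
    out$call <- ifelse(out$accepted & out$status == "ok",
                       out$label, REJECT_LABEL)
    if (!is.null(file))
        utils::write.table(out, file, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    out
}
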