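#' Optimization settings
#'
#' @param learning_rate Adam step size.
#' @param batch_size Mini-batch size.
#' @param epochs Number of passes over the training reads (>= 1).
#' @param oe_lambda Coefficient of the Outlier Exposure penalty
#'   (default 0.5). With `oe_lambda = 0` the objective reduces exactly to
#'   plain cross-entropy.
#' @param oe_enabled Train with the Outlier Exposure auxiliary loss? If
#'   `TRUE`, every in-distribution mini-batch is paired with an equal-size
#'   outlier mini-batch sampled with replacement.
#' @param holdout_fraction Fraction of in-distribution reads held out for
#'   the per-epoch accuracy trajectory (0 disables the holdout).
#' @param augment_error_rates Per-base error rates of the simulated read
#'   sets a pipeline should pool into the training data (default
#'   `c(0, 0.10)`: error-free reads plus 10%-error reads, the augmented
#'   training mix). Consumed by the pipeline driver, not by [trainModel()]
#'   itself.
#' @param seed Integer seed; training is reproducible given it
#'   (single-threaded).
#' @return A validated list of class `trainConfig`.
#' @export
trainConfig <- function(learning_rate = 1e-3, batch_size = 64L,
                        epochs = 10L, oe_lambda = 0.5, oe_enabled = FALSE,
                        holdout_fraction = 0.1,
                        augment_error_rates = c(0, 0.10), seed = 1L) {
    cfg <- list(learning_rate = learning_rate,
                batch_size = as.integer(batch_size),
                epochs = as.integer(epochs),
                oe_lambda = oe_lambda, oe_enabled = isTRUE(oe_enabled),
                holdout_fraction = holdout_fraction,
                augment_error_rates = augment_error_rates,
                seed = as.integer(seed))
    if (cfg$oe_lambda < 0) stop("oe_lambda must be >= 0")
    if (cfg$epochs < 1L) stop("epochs must be >= 1")
    if (cfg$holdout_fraction < 0 || cfg$holdout_fraction >= 0.5)
        stop("holdout_fraction must be in [0, 0.5)")
    class(cfg) <- c("trainConfig", "list")
    cfg
}

.EPS_LOG <- 1e-12  # log clamp in both losses; bias far below tolerance

#' Cross-entropy loss of one prediction
#'
#' `-ln p[label]`, with the probability clamped to `[1e-12, 1]`.
#'
#' @param probabilities Probability vector over the classes.
#' @param label 1-based index of the true class.
#' @return Non-negative scalar.
#' @examples
#' crossEntropyLoss(c(0.25, 0.25, 0.25, 0.25), 2)  # log(4)
#' @export
crossEntropyLoss <- function(probabilities, label) {
    if (label < 1L || label > length(probabilities))
        stop("label index out of range")
    -log(min(1, max(.EPS_LOG, probabilities[label])))
}

#' Outlier Exposure penalty: KL divergence from uniform
#'
#' `KL(P || Q)` where `P` is the uniform distribution over the classes and
#' `Q` the model's softmax on an out-of-distribution read. Zero when `Q`
#' is uniform; grows without bound (up to the log clamp) as `Q` sharpens.
#' Minimizing it pushes outlier predictions toward uniform, which lowers
#' their maximum-softmax confidence.
#'
#' @param Q Probability vector over the classes.
#' @return Non-negative scalar.
#' @examples
#' oePenalty(c(0.5, 0.5))          # 0
#' oePenalty(c(0.8, 0.2))          # ~0.223
#' @export
oePenalty <- function(Q) {
    K <- length(Q)
    Qc <- pmin(1, pmax(.EPS_LOG, Q))
    sum((1 / K) * log((1 / K) / Qc))
}

#' Full training objective on a pair of mini-batches
#'
#' Mean cross-entropy over the in-distribution batch plus `lambda` times
#' the mean KL-to-uniform penalty over the outlier batch.
#'
#' @param model A [DomainCNN-class].
#' @param batch_in [ReadSet-class] of labeled in-distribution reads.
#' @param batch_out [ReadSet-class] of outlier reads, or `NULL` when
#'   `lambda = 0`.
#' @param lambda Outlier Exposure coefficient (>= 0).
#' @return Scalar objective value.
#' @export
totalObjective <- function(model, batch_in, batch_out = NULL, lambda = 0.5) {
    stopifnot(is(model, "DomainCNN"), is(batch_in, "ReadSet"))
    ln <- if (length(model@labelNames)) model@labelNames else
        labelNames(batch_in)
    lab <- match(readLabels(batch_in), ln)
    if (anyNA(lab)) stop("batch_in contains labels unknown to the model")
    ce <- vapply(seq_len(length(batch_in)), function(i) {
        p <- forwardProbs(model, as.character(reads(batch_in)[[i]]))
        if (is.null(p)) stop("read too short for the model's filters")
        crossEntropyLoss(p, lab[i])
    }, 0)
    obj <- mean(ce)
    if (lambda > 0) {
        if (is.null(batch_out) || length(batch_out) == 0L)
            stop("lambda > 0 requires a non-empty outlier batch")
        oe <- vapply(seq_len(length(batch_out)), function(i)
            oePenalty(forwardProbs(model,
                as.character(reads(batch_out)[[i]]))), 0)
        obj <- obj + lambda * mean(oe)
    }
    obj
}

# ---- parameter-structure arithmetic --------------------------------------

# apply f leaf-wise over parallel parameter structures
.pmap <- function(f, ...) {
    xs <- list(...)
    if (is.list(xs[[1]])) {
        keys <- names(xs[[1]]) %||% seq_along(xs[[1]])
        out <- vector("list", length(keys))
        names(out) <- names(xs[[1]])
        for (i in seq_along(keys))
            out[[i]] <- do.call(.pmap,
                c(list(f), lapply(xs, `[[`, keys[[i]])))
        out
    } else f(...)
}

.zeroLike <- function(p) .pmap(function(x) x * 0, p)

#' Train the network
#'
#' Mini-batch Adam on the cross-entropy objective, optionally augmented
#' with the Outlier Exposure penalty: each in-distribution mini-batch is
#' then paired with an equal-size batch of outlier reads drawn with
#' replacement, and the gradient of
#' `mean CE + lambda * mean KL(uniform || softmax)` is followed.
#' Reads are consumed on the plus strand as given (strand handling is the
#' predictor's job). Deterministic given `config$seed`.
#'
#' @param model An initialized [DomainCNN-class] whose `n_classes` matches
#'   the number of families in `d_in`.
#' @param d_in [ReadSet-class] of labeled in-distribution reads covering
#'   every class.
#' @param d_out Optional [ReadSet-class] of outlier reads; required when
#'   `config$oe_enabled`.
#' @param config A [trainConfig()].
#' @return A list of class `trainResult`: `model` (trained
#'   [DomainCNN-class] with `labelNames` filled in), `loss` (per-epoch mean
#'   objective), `holdout_accuracy` (per-epoch), `train_accuracy` (final,
#'   plus-strand evaluation on the training reads).
#' @export
trainModel <- function(model, d_in, d_out = NULL, config = trainConfig()) {
    stopifnot(is(model, "DomainCNN"), is(d_in, "ReadSet"),
              inherits(config, "trainConfig"))
    cfg <- model@config
    classes <- labelNames(d_in)
    if (length(classes) != cfg$n_classes)
        stop(sprintf("model expects %d classes but d_in has %d",
                     cfg$n_classes, length(classes)))
    lab_all <- match(readLabels(d_in), classes)
    if (anyNA(lab_all)) stop("d_in contains outlier-labeled reads")
    if (!all(seq_along(classes) %in% lab_all))
        stop("every class must be represented in d_in")
    if (config$oe_enabled && (is.null(d_out) || length(d_out) == 0L))
        stop("oe_enabled requires a non-empty d_out")

    seqs <- as.character(reads(d_in))
    codes_all <- lapply(seqs, function(s) .codesFor(cfg, s))
    codes_out <- if (config$oe_enabled)
        lapply(as.character(reads(d_out)), function(s) .codesFor(cfg, s))

    params <- model@params
    K <- cfg$n_classes
    lr <- config$learning_rate
    beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8

    res <- .withSeed(config$seed, {
        n <- length(codes_all)
        n_hold <- floor(config$holdout_fraction * n)
        hold <- if (n_hold > 0) sample.int(n, n_hold) else integer(0)
        tr <- setdiff(seq_len(n), hold)
        if (!all(seq_len(K) %in% lab_all[tr]))
            stop("holdout split removed a class from the training portion; ",
                 "lower holdout_fraction or supply more reads")

        mstate <- .zeroLike(params); vstate <- .zeroLike(params)
        step <- 0L
        D <- length(.geom(cfg)$s2) * cfg$n_filters2 * .geom(cfg)$branches
        loss_hist <- numeric(config$epochs)
        acc_hist <- rep(NA_real_, config$epochs)

        for (ep in seq_len(config$epochs)) {
            ord <- sample(tr)
            batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
            ep_loss <- 0
            for (b in batches) {
                gacc <- .zeroLike(params)
                b_loss <- 0
                for (i in b) {
                    dm <- if (cfg$dropout > 0)
                        (stats::runif(D) >= cfg$dropout) / (1 - cfg$dropout)
                    fw <- .forwardCodes(params, cfg, codes_all[[i]],
                                        dropmask = dm, keep = TRUE)
                    if (is.null(fw)) next
                    y <- lab_all[i]
                    b_loss <- b_loss +
                        crossEntropyLoss(fw$probs, y) / length(b)
                    dlog <- fw$probs
                    dlog[y] <- dlog[y] - 1
                    g <- .backwardCodes(params, cfg, fw, dlog / length(b))
                    gacc <- .pmap(`+`, gacc, g)
                }
                if (config$oe_enabled) {
                    ob <- sample.int(length(codes_out), length(b),
                                     replace = TRUE)
                    lam <- config$oe_lambda
                    for (i in ob) {
                        dm <- if (cfg$dropout > 0)
                            (stats::runif(D) >= cfg$dropout) /
                                (1 - cfg$dropout)
                        fw <- .forwardCodes(params, cfg, codes_out[[i]],
                                            dropmask = dm, keep = TRUE)
                        if (is.null(fw)) next
                        b_loss <- b_loss +
                            lam * oePenalty(fw$probs) / length(ob)
                        dlog <- lam * (fw$probs - 1 / K) / length(ob)
                        g <- .backwardCodes(params, cfg, fw, dlog)
                        gacc <- .pmap(`+`, gacc, g)
                    }
                }
                step <- step + 1L
                mstate <- .pmap(function(m, g) beta1 * m + (1 - beta1) * g,
                                mstate, gacc)
                vstate <- .pmap(function(v, g) beta2 * v + (1 - beta2) * g^2,
                                vstate, gacc)
                c1 <- 1 - beta1^step; c2 <- 1 - beta2^step
                params <- .pmap(function(p, m, v)
                    p - lr * (m / c1) / (sqrt(v / c2) + adam_eps),
                    params, mstate, vstate)
                ep_loss <- ep_loss + b_loss
            }
            loss_hist[ep] <- ep_loss / length(batches)
            if (length(hold)) {
                pred <- vapply(hold, function(i) {
                    fw <- .forwardCodes(params, cfg, codes_all[[i]])
                    if (is.null(fw)) NA_integer_ else which.max(fw$probs)
                }, 1L)
                acc_hist[ep] <- mean(pred == lab_all[hold], na.rm = TRUE)
            }
        }
        list(params = params, loss = loss_hist, acc = acc_hist)
    })

    fitted <- new("DomainCNN", config = cfg, params = res$params,
                  labelNames = classes, trained = TRUE,
                  version = model@version)
    pred_tr <- vapply(seq_along(codes_all), function(i) {
        fw <- .forwardCodes(res$params, cfg, codes_all[[i]])
        if (is.null(fw)) NA_integer_ else which.max(fw$probs)
    }, 1L)
    out <- list(model = fitted, loss = res$loss,
                holdout_accuracy = res$acc,
                train_accuracy = mean(pred_tr == lab_all, na.rm = TRUE))
    class(out) <- c("trainResult", "list")
    out
}

#' @export
print.trainResult <- function(x, ...) {
    cat(sprintf(
        "trainResult: %d epoch(s); final loss %.4f; train acc %.3f%s\n",
        length(x$loss), x$loss[length(x$loss)], x$train_accuracy,
        if (!all(is.na(x$holdout_accuracy)))
            sprintf("; holdout acc %.3f",
                    x$holdout_accuracy[length(x$holdout_accuracy)]) else ""))
    invisible(x)
}
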