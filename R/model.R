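#' Architecture configuration for the domain-classification network
#'
#' The network applies a first convolutional layer of `n_filters1` filters
#' of size `filter_size1` (in codons) to the 3-channel one-hot tensor,
#' merging the three frame channels; a second convolutional layer with
#' several filter sizes (`filter_sizes2` x `n_filters2` filters each)
#' extracts longer-range patterns from the first layer's feature map;
#' max-over-time pooling, dropout, and a two-layer softmax classifier
#' follow. Defaults are the full-scale architecture: 128 size-3 conv1
#' filters, conv2 sizes `[8,12,16,20,24,28,32,36]` with 256 filters each
#' (2048 total, beyond which returns saturate), hidden width 512.
#'
#' @param variant `"three_frame"` (default; 3-channel tensor merged by the
#'   first layer), `"dna_onehot"` (raw `L x 4` DNA one-hot, all filter sizes
#'   tripled internally to cover the same sequence span) or `"three_branch"`
#'   (each frame processed by its own branch with shared weights, merged
#'   before the classifier).
#' @param filter_size1,n_filters1 First convolutional layer (codon units).
#' @param filter_sizes2,n_filters2 Second layer: vector of sizes and filter
#'   count per size.
#' @param hidden_units Width of the hidden classifier layer.
#' @param n_classes Number of domain families (>= 2).
#' @param dropout Dropout probability after pooling, in `[0, 1)`.
#' @param window Fixed encoder window in codons (3000 nt / 3).
#' @param extra_layer If `TRUE`, insert an additional convolutional layer of
#'   64 size-3 filters between the two standard layers (depth ablation).
#' @return A named list of class `cnnConfig`.
#' @examples
#' cnnConfig(n_classes = 5)
#' @export
cnnConfig <- function(variant = c("three_frame", "dna_onehot", "three_branch"),
                      filter_size1 = 3L, n_filters1 = 128L,
                      filter_sizes2 = c(8L, 12L, 16L, 20L, 24L, 28L, 32L, 36L),
                      n_filters2 = 256L, hidden_units = 512L,
                      n_classes = 2L, dropout = 0.5, window = 1000L,
                      extra_layer = FALSE) {
    variant <- match.arg(variant)
    cfg <- list(variant = variant,
                filter_size1 = as.integer(filter_size1),
                n_filters1 = as.integer(n_filters1),
                filter_sizes2 = as.integer(filter_sizes2),
                n_filters2 = as.integer(n_filters2),
                hidden_units = as.integer(hidden_units),
                n_classes = as.integer(n_classes),
                dropout = dropout,
                window = as.integer(window),
                extra_layer = isTRUE(extra_layer))
    if (cfg$n_classes < 2L) stop("n_classes must be >= 2")
    if (cfg$dropout < 0 || cfg$dropout >= 1) stop("dropout must be in [0, 1)")
    if (any(c(cfg$filter_size1, cfg$filter_sizes2, cfg$n_filters1,
              cfg$n_filters2, cfg$hidden_units) < 1L))
        stop("filter sizes and counts must be >= 1")
    class(cfg) <- c("cnnConfig", "list")
    cfg
}

#' Desk-scale architecture
#'
#' A scaled-down configuration for small synthetic benchmarks and tests:
#' 16 size-3 conv1 filters, conv2 sizes `[8,12,16]` x 16 filters, hidden
#' width 64, dropout 0.3. A handful of families with planted motifs needs
#' far fewer features than the 86-class full-scale problem, and the small
#' pooled-feature vector tolerates less dropout than the full-width model.
#'
#' @inheritParams cnnConfig
#' @param ... Further arguments passed to [cnnConfig()].
#' @return A `cnnConfig` list.
#' @export
deskCnnConfig <- function(n_classes = 2L, window = 150L, dropout = 0.3,
                          ...) {
    cnnConfig(n_filters1 = 16L, filter_sizes2 = c(8L, 12L, 16L),
              n_filters2 = 16L, hidden_units = 64L, dropout = dropout,
              n_classes = n_classes, window = window, ...)
}

# ---- internal geometry helpers -------------------------------------------

# effective channel count / alphabet / conv sizes for a variant
.geom <- function(cfg) {
    switch(cfg$variant,
        three_frame = list(C = 3L, A = 21L, branches = 1L,
                           h1 = cfg$filter_size1, s2 = cfg$filter_sizes2),
        three_branch = list(C = 1L, A = 21L, branches = 3L,
                            h1 = cfg$filter_size1, s2 = cfg$filter_sizes2),
        dna_onehot = list(C = 1L, A = 4L, branches = 1L,
                          h1 = 3L * cfg$filter_size1,
                          s2 = 3L * cfg$filter_sizes2))
}

#' Initialize an untrained model
#'
#' He-style random initialization (`N(0, 2/fan_in)` weights, zero biases),
#' reproducible given `seed`.
#'
#' @param config A [cnnConfig()].
#' @param seed Integer seed.
#' @return An untrained [DomainCNN-class].
#' @examples
#' m <- initModel(deskCnnConfig(n_classes = 3), seed = 1)
#' m
#' @export
initModel <- function(config, seed = 1L) {
    stopifnot(inherits(config, "cnnConfig"))
    g <- .geom(config)
    he <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / nr)),
                                  nr, nc)
    params <- .withSeed(seed, {
        p <- list(W1 = he(g$C * g$h1 * g$A, config$n_filters1),
                  b1 = numeric(config$n_filters1))
        Fpre <- config$n_filters1
        if (config$extra_layer) {
            p$W1b <- he(3L * Fpre, 64L)
            p$b1b <- numeric(64L)
            Fpre <- 64L
        }
        p$W2 <- lapply(g$s2, function(s) he(s * Fpre, config$n_filters2))
        p$b2 <- lapply(g$s2, function(s) numeric(config$n_filters2))
        D <- g$branches * length(g$s2) * config$n_filters2
        p$Wh <- he(D, config$hidden_units)
        p$bh <- numeric(config$hidden_units)
        p$Wo <- he(config$hidden_units, config$n_classes)
        p$bo <- numeric(config$n_classes)
        p
    })
    new("DomainCNN", config = unclass(config), params = params,
        labelNames = character(0), trained = FALSE, version = "domainCNN/1")
}

#' Number of learnable parameters
#'
#' @param model A [DomainCNN-class].
#' @return Integer count over all weight matrices and bias vectors.
#' @export
nParameters <- function(model) {
    stopifnot(is(model, "DomainCNN"))
    sum(rapply(model@params, length, how = "unlist"))
}

# ---- Eq.-style single-filter convolution ---------------------------------

#' Single-filter multi-channel convolution feature map
#'
#' The elementary operation of the first convolutional layer: for each
#' window position `i`, the feature value is
#' `c_i = ReLU( sum_j <w_j, arr[j, i:(i+h-1), ]> + b )`,
#' summing the per-channel inner products of the filter's three `h x 21`
#' matrices with the corresponding tensor window.
#'
#' @param arr Encoded tensor of dim `c(3, n, 21)` from [encode3Frame()].
#' @param filters A list of three `h x 21` matrices, or an array
#'   `c(3, h, 21)`.
#' @param bias Scalar bias term.
#' @return Numeric vector of the `n - h + 1` feature values.
#' @export
convFeature <- function(arr, filters, bias = 0) {
    stopifnot(length(dim(arr)) == 3L, dim(arr)[1] == 3L, dim(arr)[3] == 21L)
    if (is.array(filters) && length(dim(filters)) == 3L)
        filters <- lapply(1:3, function(j) filters[j, , , drop = TRUE])
    stopifnot(length(filters) == 3L)
    h <- nrow(filters[[1]])
    n <- dim(arr)[2]
    if (h > n) stop("filter size exceeds the tensor window")
    V <- n - h + 1L
    # im2col: row i is the flattened (channel, within-window position) block
    X <- matrix(0, V, 3L * h * 21L)
    for (j in 1:3) {
        m <- matrix(arr[j, , ], nrow = n)
        for (k in seq_len(h)) {
            cols <- ((j - 1L) * h + (k - 1L)) * 21L + 1:21
            X[, cols] <- m[k:(k + V - 1L), , drop = FALSE]
        }
    }
    w <- unlist(lapply(filters, function(f) as.vector(t(f))))
    .relu(drop(X %*% w) + bias)
}

# ---- fast internal forward / backward ------------------------------------

# integer-coded channels for a model variant; frame_order permutes the
# three translation channels (test-time frame-order experiments)
.codesFor <- function(cfg, dna, frame_order = 1:3) {
    if (cfg$variant == "dna_onehot") .dnaCodes(dna)
    else .frameCodes(dna)[frame_order]
}

# build the im2col matrix for codes of C channels with filter span h over
# alphabet A; V rows. codes entries of 0 (unknown DNA base) leave zero rows.
.im2colCodes <- function(codes, h, A, V) {
    C <- length(codes)
    X <- matrix(0, V, C * h * A)
    rows <- seq_len(V)
    for (j in seq_len(C)) {
        cj <- codes[[j]]
        for (k in seq_len(h)) {
            v <- cj[(k - 1L) + rows]
            ok <- which(v > 0L)
            if (length(ok))
                X[cbind(ok, ((j - 1L) * h + (k - 1L)) * A + v[ok])] <- 1
        }
    }
    X
}

# im2col over a dense feature map M (V1 x F): rows are s-long column blocks
.im2colMap <- function(M, s, V2) {
    Fp <- ncol(M)
    X <- matrix(0, V2, s * Fp)
    for (k in seq_len(s))
        X[, ((k - 1L) * Fp + 1L):(k * Fp)] <- M[k:(k + V2 - 1L), ,
                                                drop = FALSE]
    X
}

# forward through one convolutional branch; returns pooled features + cache
# codes: list of C integer vectors; returns NULL when too short for conv1
# or for every conv2 size
.branchForward <- function(params, cfg, g, codes, keep = FALSE) {
    # the window cap is in codon positions; the raw-DNA variant works in
    # nucleotide positions, so its cap is three times larger
    cap <- if (cfg$variant == "dna_onehot") 3L * cfg$window else cfg$window
    lens <- pmin(lengths(codes), cap)
    V1 <- min(lens) - g$h1 + 1L
    if (V1 < 1L) return(NULL)
    codes <- lapply(codes, function(x) x[seq_len(min(length(x), cap))])
    X1 <- .im2colCodes(codes, g$h1, g$A, V1)
    S1 <- sweep(X1 %*% params$W1, 2L, params$b1, "+")
    A1 <- .relu(S1)
    pre <- A1; Xb <- NULL
    if (isTRUE(cfg$extra_layer)) {
        Vb <- V1 - 3L + 1L
        if (Vb < 1L) return(NULL)
        Xb <- .im2colMap(A1, 3L, Vb)
        pre <- .relu(sweep(Xb %*% params$W1b, 2L, params$b1b, "+"))
    }
    Vp <- nrow(pre)
    F2 <- cfg$n_filters2
    nsz <- length(g$s2)
    pooled <- numeric(nsz * F2)
    argm <- rep(NA_integer_, nsz * F2)
    X2s <- vector("list", nsz)
    any_valid <- FALSE
    for (k in seq_len(nsz)) {
        s <- g$s2[k]
        V2 <- Vp - s + 1L
        if (V2 < 1L) next                     # size inactive for this read
        any_valid <- TRUE
        X2 <- .im2colMap(pre, s, V2)
        Z <- .relu(sweep(X2 %*% params$W2[[k]], 2L, params$b2[[k]], "+"))
        a <- max.col(t(Z), ties.method = "first")
        idx <- (k - 1L) * F2 + seq_len(F2)
        pooled[idx] <- Z[cbind(a, seq_len(F2))]
        argm[idx] <- a
        if (keep) X2s[[k]] <- X2
    }
    if (!any_valid) return(NULL)
    out <- list(pooled = pooled, argmax = argm)
    if (keep) {
        out$X1 <- X1; out$A1 <- A1; out$X2 <- X2s
        out$Xb <- Xb; out$pre <- pre
    }
    out
}

# full eval/train forward; returns NULL for too-short reads
# dropout mask is drawn by the caller (training loop) for reproducibility
.forwardCodes <- function(params, cfg, codes, dropmask = NULL, keep = FALSE) {
    g <- .geom(cfg)
    branches <- if (g$branches == 1L) list(codes) else
        lapply(codes, list)
    bouts <- lapply(branches, function(b)
        .branchForward(params, cfg, g, b, keep = keep))
    if (any(vapply(bouts, is.null, TRUE))) return(NULL)
    u <- unlist(lapply(bouts, `[[`, "pooled"))
    ud <- if (is.null(dropmask)) u else u * dropmask
    hpre <- drop(ud %*% params$Wh) + params$bh
    h <- .relu(hpre)
    logits <- drop(h %*% params$Wo) + params$bo
    probs <- .softmax(logits)
    out <- list(probs = probs, logits = logits, pooled = u)
    if (keep) {
        out$branches <- bouts; out$u <- u; out$ud <- ud; out$h <- h
        out$dropmask <- dropmask
    }
    out
}

# backward pass given dlogits; returns gradient list matching params.
# fw must come from .forwardCodes(..., keep = TRUE)
.backwardCodes <- function(params, cfg, fw, dlogits) {
    g <- .geom(cfg)
    grad <- list()
    grad$Wo <- outer(fw$h, dlogits)
    grad$bo <- dlogits
    dh <- drop(params$Wo %*% dlogits) * (fw$h > 0)
    grad$Wh <- outer(fw$ud, dh)
    grad$bh <- dh
    du <- drop(params$Wh %*% dh)
    if (!is.null(fw$dropmask)) du <- du * fw$dropmask

    F2 <- cfg$n_filters2
    nsz <- length(g$s2)
    Ftot <- nsz * F2
    zW1 <- matrix(0, nrow(params$W1), ncol(params$W1))
    grad$W1 <- zW1; grad$b1 <- numeric(ncol(params$W1))
    if (isTRUE(cfg$extra_layer)) {
        grad$W1b <- matrix(0, nrow(params$W1b), ncol(params$W1b))
        grad$b1b <- numeric(ncol(params$W1b))
    }
    grad$W2 <- lapply(params$W2, function(w) matrix(0, nrow(w), ncol(w)))
    grad$b2 <- lapply(params$b2, function(b) numeric(length(b)))

    for (br in seq_along(fw$branches)) {
        bo <- fw$branches[[br]]
        du_b <- du[(br - 1L) * Ftot + seq_len(Ftot)]
        Fpre <- ncol(bo$pre)
        dpre <- matrix(0, nrow(bo$pre), Fpre)
        for (k in seq_len(nsz)) {
            idx <- (k - 1L) * F2 + seq_len(F2)
            a <- bo$argmax[idx]
            if (all(is.na(a))) next
            # ReLU subgradient: pooled == 0 means no window activated
            dz <- du_b[idx] * (bo$pooled[idx] > 0)
            live <- which(dz != 0 & !is.na(a))
            if (!length(live)) next
            X2 <- bo$X2[[k]]
            rows <- X2[a[live], , drop = FALSE]
            grad$W2[[k]][, live] <- grad$W2[[k]][, live, drop = FALSE] +
                t(rows * dz[live])
            grad$b2[[k]][live] <- grad$b2[[k]][live] + dz[live]
            G <- matrix(0, nrow(X2), F2)
            G[cbind(a[live], live)] <- dz[live]
            dX2 <- G %*% t(params$W2[[k]])
            s <- g$s2[k]
            for (p in seq_len(s)) {
                cols <- ((p - 1L) * Fpre + 1L):(p * Fpre)
                rng <- p:(p + nrow(X2) - 1L)
                dpre[rng, ] <- dpre[rng, , drop = FALSE] +
                    dX2[, cols, drop = FALSE]
            }
        }
        if (isTRUE(cfg$extra_layer)) {
            dpre <- dpre * (bo$pre > 0)
            grad$W1b <- grad$W1b + crossprod(bo$Xb, dpre)
            grad$b1b <- grad$b1b + colSums(dpre)
            dXb <- dpre %*% t(params$W1b)
            F1 <- ncol(bo$A1)
            dA1 <- matrix(0, nrow(bo$A1), F1)
            for (p in 1:3) {
                cols <- ((p - 1L) * F1 + 1L):(p * F1)
                rng <- p:(p + nrow(dXb) - 1L)
                dA1[rng, ] <- dA1[rng, , drop = FALSE] +
                    dXb[, cols, drop = FALSE]
            }
        } else dA1 <- dpre
        dA1 <- dA1 * (bo$A1 > 0)
        grad$W1 <- grad$W1 + crossprod(bo$X1, dA1)
        grad$b1 <- grad$b1 + colSums(dA1)
    }
    grad
}

#' Forward pass: class probabilities for one input
#'
#' Evaluation-mode forward pass (dropout disabled). Accepts either a DNA
#' string, which is encoded internally, or a pre-built tensor from
#' [encode3Frame()] (its trailing all-zero padding rows are ignored, so
#' outputs are independent of pad length).
#'
#' @param model A [DomainCNN-class].
#' @param x A single DNA string, or a `c(3, n, 21)` encoded tensor.
#' @return Numeric probability vector over the model's classes (sums to 1),
#'   or `NULL` when the input is shorter than the smallest filter span.
#' @export
forwardProbs <- function(model, x) {
    stopifnot(is(model, "DomainCNN"))
    cfg <- model@config
    codes <- if (is.character(x)) .codesFor(cfg, x)
        else {
            if (cfg$variant == "dna_onehot")
                stop("tensor input is only defined for the 3-frame variants")
            .decodeTensor(x)
        }
    fw <- .forwardCodes(model@params, cfg, codes)
    if (is.null(fw)) return(NULL)
    p <- fw$probs
    names(p) <- if (length(model@labelNames)) model@labelNames else NULL
    p
}
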