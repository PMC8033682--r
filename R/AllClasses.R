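#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom Biostrings DNAStringSet AAStringSet
NULL

#' Label used for reads that carry no trained domain family
#'
#' Out-of-distribution ("outlier") reads are tagged with this sentinel label
#' in a [ReadSet] and by [detect()] when a read is rejected.
#' @export
OUTLIER_LABEL <- "OUTLIER"

#' Label emitted for rejected reads
#' @rdname OUTLIER_LABEL
#' @export
REJECT_LABEL <- "REJECT"

#' ReadSet: labeled DNA reads
#'
#' A container pairing a [Biostrings::DNAStringSet] of reads with per-read
#' metadata: the true family label (or `"OUTLIER"`), strand of origin,
#' start/end on the source reference and, for simulated reads, the exact
#' number of substitution/insertion/deletion errors injected (construction
#' bookkeeping used to calibrate the simulator without an aligner).
#'
#' @slot reads A `DNAStringSet`; names are read identifiers.
#' @slot info A `DataFrame` with one row per read. Always contains a
#'   `label` column; simulated reads add `strand`, `ref`, `start`, `end`,
#'   `n_sub`, `n_ins`, `n_del`.
#' @slot labelNames Character vector of family identifiers indexed by the
#'   non-outlier labels.
#' @export
setClass("ReadSet",
    representation(
        reads = "DNAStringSet",
        info = "DataFrame",
        labelNames = "character"
    )
)

setValidity("ReadSet", function(object) {
    msg <- character()
    if (length(object@reads) != nrow(object@info))
        msg <- c(msg, "length(reads) must equal nrow(info)")
    if (!"label" %in% colnames(object@info))
        msg <- c(msg, "info must contain a 'label' column")
    else {
        lab <- object@info$label
        bad <- !(lab %in% c(object@labelNames, OUTLIER_LABEL))
        if (any(bad))
            msg <- c(msg, sprintf(
                "%d read label(s) not in labelNames or '%s'",
                sum(bad), OUTLIER_LABEL))
    }
    if (length(object@reads) > 0 && any(Biostrings::width(object@reads) == 0))
        msg <- c(msg, "reads must be non-empty sequences")
    if (length(msg)) msg else TRUE
})

#' Construct a ReadSet
#'
#' @param reads A `DNAStringSet` or named character vector of DNA sequences.
#' @param label Character vector of per-read labels (family id or
#'   `"OUTLIER"`). Recycled if length 1.
#' @param labelNames Character vector of all family identifiers; defaults to
#'   the sorted unique non-outlier labels.
#' @param info Optional `DataFrame` of additional per-read columns.
#' @return A [ReadSet-class] object.
#' @examples
#' rs <- ReadSet(c(r1 = "ATGGCC", r2 = "ATGTGG"), label = "famA")
#' reads(rs)
#' @export
ReadSet <- function(reads, label, labelNames = NULL, info = NULL) {
    if (is.character(reads))
        reads <- Biostrings::DNAStringSet(reads)
    label <- rep_len(as.character(label), length(reads))
    if (is.null(labelNames))
        labelNames <- sort(unique(label[label != OUTLIER_LABEL]))
    if (is.null(info)) {
        info <- DataFrame(label = label)
    } else {
        info$label <- label
    }
    rownames(info) <- NULL
    new("ReadSet", reads = reads, info = info, labelNames = labelNames)
}

#' FamilyRef: synthetic reference protein families
#'
#' The output of [generateFamilies()]: per-family member proteins carrying
#' planted conserved motifs, their reverse-translated coding sequences, and
#' the motif ground truth used by downstream interpretation checks.
#'
#' @slot proteins `AAStringSet` of all member proteins (names are member ids).
#' @slot cds `DNAStringSet` of the members' coding sequences, frame-0
#'   translations of which recover `proteins` exactly.
#' @slot family Character vector: family id of each member.
#' @slot motifs Named list (one entry per family) with elements `seqs`
#'   (planted motif peptides) and `starts` (1-based positions in the
#'   consensus).
#' @slot consensus `AAStringSet`, one consensus protein per family.
#' @slot spec The [familySpec()] list the object was generated from.
#' @export
setClass("FamilyRef",
    representation(
        proteins = "AAStringSet",
        cds = "DNAStringSet",
        family = "character",
        motifs = "list",
        consensus = "AAStringSet",
        spec = "list"
    )
)

setValidity("FamilyRef", function(object) {
    msg <- character()
    n <- length(object@proteins)
    if (length(object@cds) != n || length(object@family) != n)
        msg <- c(msg, "proteins, cds and family must have equal length")
    fams <- names(object@motifs)
    if (!setequal(fams, unique(object@family)))
        msg <- c(msg, "motifs must be named by the family ids")
    if (length(msg)) msg else TRUE
})

#' DomainCNN: the read-classification network
#'
#' Holds the architecture description (`config`) and the learned parameters
#' (`params`) of the two-convolutional-layer network with max-over-time
#' pooling and a two-layer softmax classifier. Created untrained by
#' [initModel()] and fitted by [trainModel()].
#'
#' @slot config Named list: `variant` (`"three_frame"`, `"dna_onehot"` or
#'   `"three_branch"`), `filter_size1`, `n_filters1`, `filter_sizes2`,
#'   `n_filters2`, `hidden_units`, `n_classes`, `dropout`, `window` (codons),
#'   `extra_layer`.
#' @slot params Named list of weight matrices and bias vectors.
#' @slot labelNames Class identifiers, filled in at training time.
#' @slot trained Logical.
#' @slot version Serialization format tag checked by [loadModel()].
#' @export
setClass("DomainCNN",
    representation(
        config = "list",
        params = "list",
        labelNames = "character",
        trained = "logical",
        version = "character"
    )
)

setValidity("DomainCNN", function(object) {
    msg <- character()
    cfg <- object@config
    need <- c("variant", "filter_size1", "n_filters1", "filter_sizes2",
              "n_filters2", "hidden_units", "n_classes", "dropout", "window")
    miss <- setdiff(need, names(cfg))
    if (length(miss))
        msg <- c(msg, paste("config missing:", paste(miss, collapse = ", ")))
    else {
        if (cfg$n_classes < 2) msg <- c(msg, "n_classes must be >= 2")
        if (cfg$dropout < 0 || cfg$dropout >= 1)
            msg <- c(msg, "dropout must be in [0, 1)")
        if (any(c(cfg$filter_size1, cfg$filter_sizes2) < 1))
            msg <- c(msg, "filter sizes must be >= 1")
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn ReadSet-class Number of reads.
#' @param x,object A `ReadSet`.
#' @export
setMethod("length", "ReadSet", function(x) length(x@reads))

#' @describeIn ReadSet-class Subset reads.
#' @param i Index vector.
#' @param j,...,drop Ignored.
#' @export
setMethod("[", "ReadSet", function(x, i, j, ..., drop = FALSE) {
    new("ReadSet", reads = x@reads[i], info = x@info[i, , drop = FALSE],
        labelNames = x@labelNames)
})

setGeneric("reads", function(x) standardGeneric("reads"))
setGeneric("readInfo", function(x) standardGeneric("readInfo"))
setGeneric("readLabels", function(x) standardGeneric("readLabels"))
setGeneric("labelNames", function(x) standardGeneric("labelNames"))
setGeneric("modelConfig", function(x) standardGeneric("modelConfig"))
setGeneric("modelParams", function(x) standardGeneric("modelParams"))
setGeneric("isTrained", function(x) standardGeneric("isTrained"))
setGeneric("familyMotifs", function(x) standardGeneric("familyMotifs"))
setGeneric("referenceCDS", function(x) standardGeneric("referenceCDS"))
setGeneric("referenceProteins", function(x) standardGeneric("referenceProteins"))
setGeneric("referenceFamily", function(x) standardGeneric("referenceFamily"))

#' @describeIn ReadSet-class The underlying `DNAStringSet`.
#' @export
setMethod("reads", "ReadSet", function(x) x@reads)

#' @describeIn ReadSet-class Per-read metadata `DataFrame`.
#' @export
setMethod("readInfo", "ReadSet", function(x) x@info)

#' @describeIn ReadSet-class Character vector of per-read labels.
#' @export
setMethod("readLabels", "ReadSet", function(x) x@info$label)

#' @describeIn ReadSet-class Family identifiers.
#' @export
setMethod("labelNames", "ReadSet", function(x) x@labelNames)

#' @describeIn DomainCNN-class Architecture description list.
#' @param x,object A `DomainCNN`.
#' @export
setMethod("modelConfig", "DomainCNN", function(x) x@config)

#' @describeIn DomainCNN-class Learned parameter list.
#' @export
setMethod("modelParams", "DomainCNN", function(x) x@params)

#' @describeIn DomainCNN-class Has the model been fitted?
#' @export
setMethod("isTrained", "DomainCNN", function(x) x@trained)

#' @describeIn DomainCNN-class Class identifiers the model predicts.
#' @export
setMethod("labelNames", "DomainCNN", function(x) x@labelNames)

#' @describeIn FamilyRef-class Planted-motif ground truth per family.
#' @param x,object A `FamilyRef`.
#' @export
setMethod("familyMotifs", "FamilyRef", function(x) x@motifs)

#' @describeIn FamilyRef-class Member coding sequences.
#' @export
setMethod("referenceCDS", "FamilyRef", function(x) x@cds)

#' @describeIn FamilyRef-class Member proteins.
#' @export
setMethod("referenceProteins", "FamilyRef", function(x) x@proteins)

#' @describeIn FamilyRef-class Family id of each member.
#' @export
setMethod("referenceFamily", "FamilyRef", function(x) x@family)

setMethod("show", "ReadSet", function(object) {
    lab <- readLabels(object)
    n_out <- sum(lab == OUTLIER_LABEL)
    cat(sprintf("ReadSet with %d read(s), %d family label(s), %d outlier(s)\n",
        length(object), length(object@labelNames), n_out))
    if (length(object)) {
        w <- Biostrings::width(object@reads)
        cat(sprintf("  read length: %d-%d nt (median %d)\n",
            min(w), max(w), as.integer(stats::median(w))))
    }
})

setMethod("show", "FamilyRef", function(object) {
    cat(sprintf(
        "FamilyRef: %d families, %d member proteins (%d aa), %d motif(s)/family\n",
        length(object@motifs), length(object@proteins),
        object@spec$protein_length, object@spec$motifs_per_family))
})

setMethod("show", "DomainCNN", function(object) {
    cfg <- object@config
    cat(sprintf("DomainCNN [%s] %s\n", cfg$variant,
        if (object@trained) "(trained)" else "(untrained)"))
    cat(sprintf("  conv1: %d filters of size %d\n",
        cfg$n_filters1, cfg$filter_size1))
    cat(sprintf("  conv2: sizes [%s] x %d filters each\n",
        paste(cfg$filter_sizes2, collapse = ","), cfg$n_filters2))
    cat(sprintf("  hidden %d -> %d classes; dropout %.2f; window %d codons\n",
        cfg$hidden_units, cfg$n_classes, cfg$dropout, cfg$window))
    cat(sprintf("  parameters: %s\n",
        format(nParameters(object), big.mark = ",")))
})
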