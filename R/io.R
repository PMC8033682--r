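#' Read DNA sequences from FASTA or FASTQ
#'
#' Format is auto-detected from the file extension (`.fq`/`.fastq` vs
#' anything else) unless given explicitly. Sequences are upper-cased and
#' RNA `U` is mapped to `T`; qualities in FASTQ are ignored. Labels, if
#' available, come from a sidecar TSV (see `labels_file`) or from a
#' `"id|label"` FASTA header convention.
#'
#' @param path Input file.
#' @param format `"auto"`, `"fasta"` or `"fastq"`.
#' @param labels_file Optional TSV with columns `read_id` and `label`.
#' @return A [ReadSet-class]; reads without label information are labeled
#'   `"OUTLIER"` only if the sidecar says so, otherwise they get the
#'   placeholder label `"unlabeled"`... see Details.
#' @details When neither a sidecar nor header labels exist, all labels are
#'   set to `"OUTLIER"`-free placeholder `"unknown"` and `labelNames` is
#'   `"unknown"`; prediction does not use labels.
#' @export
readSequences <- function(path, format = c("auto", "fasta", "fastq"),
                          labels_file = NULL) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("file not found: ", path)
    if (format == "auto")
        format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path)) "fastq"
            else "fasta"
    # read as raw strings first: RNA 'U' and lower case are normalized
    # before imposing the DNA alphabet
    seqs <- tryCatch(
        Biostrings::readBStringSet(path, format = format),
        error = function(e) stop("malformed ", format, " in ", path, ": ",
                                 conditionMessage(e), call. = FALSE))
    chr <- toupper(chartr("Uu", "Tt", as.character(seqs)))
    ids <- sub("\\s.*$", "", names(seqs))
    lab <- rep("unknown", length(chr))
    if (!is.null(labels_file)) {
        tab <- utils::read.delim(labels_file, stringsAsFactors = FALSE)
        m <- match(ids, tab$read_id)
        lab[!is.na(m)] <- tab$label[m[!is.na(m)]]
    } else if (any(grepl("|", ids, fixed = TRUE))) {
        parts <- strsplit(ids, "|", fixed = TRUE)
        ids <- vapply(parts, `[[`, "", 1L)
        lab <- vapply(parts, function(p) if (length(p) > 1L) p[2] else
            "unknown", "")
    }
    names(chr) <- ids
    ReadSet(chr, label = lab)
}

#' Write a ReadSet to FASTA or FASTQ plus a label sidecar
#'
#' Sequence files stay standard: labels and simulation bookkeeping ride in
#' a TSV next to the sequences (`<path>.labels.tsv` by default). FASTQ
#' output uses the constant dummy quality `I`.
#'
#' @param x A [ReadSet-class].
#' @param path Output sequence file.
#' @param format `"fasta"` or `"fastq"`.
#' @param labels_file Sidecar TSV path, or `NA` to skip it.
#' @return Invisibly, `path`.
#' @export
writeReadSet <- function(x, path, format = c("fasta", "fastq"),
                         labels_file = paste0(path, ".labels.tsv")) {
    format <- match.arg(format)
    stopifnot(is(x, "ReadSet"))
    seqs <- reads(x)
    if (format == "fasta") {
        Biostrings::writeXStringSet(seqs, path)
    } else {
        qual <- Biostrings::BStringSet(
            vapply(Biostrings::width(seqs), function(w)
                strrep("I", w), ""))
        Biostrings::writeXStringSet(seqs, path, format = "fastq",
                                    qualities = qual)
    }
    if (!is.na(labels_file)) {
        info <- as.data.frame(readInfo(x))
        info <- cbind(read_id = names(seqs), info)
        utils::write.table(info, labels_file, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    invisible(path)
}

#' Write reference sequences with family labels in headers
#'
#' FASTA headers follow the `id|family` convention read back by
#' [readSequences()].
#'
#' @param ref A [FamilyRef-class].
#' @param path Output FASTA for the coding sequences.
#' @return Invisibly, `path`.
#' @export
writeReferences <- function(ref, path) {
    stopifnot(is(ref, "FamilyRef"))
    cds <- referenceCDS(ref)
    names(cds) <- sprintf("%s|%s", names(cds), referenceFamily(ref))
    Biostrings::writeXStringSet(cds, path)
    invisible(path)
}

.MODEL_VERSION <- "domainCNN/1"

#' Persist a trained model
#'
#' Model parameters, architecture config and class labels are serialized
#' together under a version tag; [loadModel()] refuses mismatched
#' versions. The config alone can additionally be dumped as YAML for
#' inspection.
#'
#' @param model A [DomainCNN-class].
#' @param path Output file.
#' @param config_yaml Optional path for a YAML dump of the architecture.
#' @return Invisibly, `path`.
#' @export
saveModel <- function(model, path, config_yaml = NULL) {
    stopifnot(is(model, "DomainCNN"))
    obj <- list(version = .MODEL_VERSION, config = model@config,
                params = model@params, labelNames = model@labelNames,
                trained = model@trained)
    saveRDS(obj, path)
    if (!is.null(config_yaml))
        yaml::write_yaml(model@config, config_yaml)
    invisible(path)
}

#' @rdname saveModel
#' @param config_only If `TRUE`, return just the architecture config list.
#' @export
loadModel <- function(path, config_only = FALSE) {
    obj <- tryCatch(readRDS(path), error = function(e)
        stop("cannot read model file ", path, ": ", conditionMessage(e),
             call. = FALSE))
    if (!is.list(obj) || !identical(obj$version, .MODEL_VERSION))
        stop("model file version mismatch (expected ", .MODEL_VERSION, ")")
    if (config_only) return(obj$config)
    new("DomainCNN", config = obj$config, params = obj$params,
        labelNames = obj$labelNames, trained = obj$trained,
        version = obj$version)
}
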