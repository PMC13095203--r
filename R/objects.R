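#' The eight subtype signature names
#'
#' Classification requires exactly these eight signatures. `ccrcc3_up` /
#' `ccrcc3_down` capture the normal kidney-like program, `ccrcc2_up`
#' angiogenesis, `ccrcc1_up` myeloid/complement programs, `ccrcc4_up`
#' pro-lymphocytic markers, `ccrcc1and4_up` proliferative/stromal programs
#' shared by the two aggressive subtypes, plus the cell-cycle and T-effector
#' programs.
#'
#' @return Character vector of length eight, in the canonical column order
#'   used by [score_all()].
#' @export
clearseq_signature_names <- function() {
  c("ccrcc3_up", "ccrcc3_down", "ccrcc2_up", "ccrcc1_up",
    "ccrcc4_up", "ccrcc1and4_up", "cell_cycle", "t_effector")
}

#' The four subtype labels
#' @return Character vector `c("ccrcc1", "ccrcc2", "ccrcc3", "ccrcc4")`.
#' @export
clearseq_subtypes <- function() paste0("ccrcc", 1:4)

# Canonical gene key: trimmed, upper-cased. Signatures are given as symbols
# while matrices may use mixed case, so all gene matching goes through this.
gene_key <- function(x) toupper(trimws(x))

#' Construct a validated count matrix
#'
#' @param counts Numeric matrix, genes in rows and samples in columns, with
#'   unique non-empty dimnames. Values must be nonnegative integers (counts).
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (integer-valued matrix), `gene_ids` and `sample_ids`.
#' @export
count_matrix <- function(counts) {
  cs_assert(is.matrix(counts), "malformed_matrix", "counts must be a matrix")
  cs_assert(nrow(counts) >= 1 && ncol(counts) >= 1, "empty_input",
            "count matrix must have at least 1 gene and 1 sample")
  cs_assert(!is.null(rownames(counts)) && !is.null(colnames(counts)),
            "malformed_matrix", "count matrix needs gene and sample names")
  gid <- trimws(rownames(counts))
  sid <- trimws(colnames(counts))
  cs_assert(!anyDuplicated(gid), "duplicate_identifier",
            "duplicate gene IDs: %s",
            paste(unique(gid[duplicated(gid)]), collapse = ", "))
  cs_assert(!anyDuplicated(sid), "duplicate_identifier",
            "duplicate sample IDs: %s",
            paste(unique(sid[duplicated(sid)]), collapse = ", "))
  cs_assert(is.numeric(counts) && !anyNA(counts), "malformed_matrix",
            "counts must be numeric with no missing values")
  cs_assert(all(counts >= 0), "malformed_matrix", "counts must be nonnegative")
  cs_assert(max(abs(counts - round(counts))) < 1e-8, "malformed_matrix",
            "counts must be integers")
  counts <- round(counts)
  if (max(counts) < .Machine$integer.max) storage.mode(counts) <- "integer"
  dimnames(counts) <- list(gid, sid)
  structure(list(counts = counts, gene_ids = gid, sample_ids = sid),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples (total counts %.3g)\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Construct an expression matrix on a variance-stabilized scale
#'
#' @param values Numeric matrix (genes x samples) of finite values on a
#'   log-like scale, with dimnames.
#' @param size_factors Positive per-sample size factors (default 1).
#' @param transform One of `"vst_closed_form"`, `"log2_norm_plus1"`,
#'   `"precomputed"`; records how `values` were obtained.
#' @param batch Optional per-sample batch labels.
#' @param batch_corrected Logical; whether batch correction was applied.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, size_factors = NULL,
                              transform = c("precomputed", "log2_norm_plus1",
                                            "vst_closed_form"),
                              batch = NULL, batch_corrected = FALSE) {
  transform <- match.arg(transform)
  cs_assert(is.matrix(values) && is.numeric(values), "malformed_matrix",
            "values must be a numeric matrix")
  cs_assert(nrow(values) >= 1 && ncol(values) >= 1, "empty_input",
            "expression matrix is empty")
  cs_assert(all(is.finite(values)), "malformed_matrix",
            "expression values must be finite")
  cs_assert(!is.null(rownames(values)) && !is.null(colnames(values)),
            "malformed_matrix", "expression matrix needs dimnames")
  if (is.null(size_factors)) size_factors <- rep(1, ncol(values))
  cs_assert(length(size_factors) == ncol(values) && all(size_factors > 0),
            "invalid_parameter", "size factors must be positive, one per sample")
  if (!is.null(batch)) {
    cs_assert(length(batch) == ncol(values), "invalid_parameter",
              "batch labels must be one per sample")
    batch <- as.character(batch)
  }
  structure(list(values = values,
                 gene_ids = rownames(values),
                 sample_ids = colnames(values),
                 size_factors = stats::setNames(as.numeric(size_factors),
                                                colnames(values)),
                 transform = transform,
                 batch = batch,
                 batch_corrected = isTRUE(batch_corrected)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples [%s%s]\n",
              nrow(x$values), ncol(x$values), x$transform,
              if (x$batch_corrected) ", batch-corrected" else ""))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Construct a signature registry
#'
#' @param signatures Named list of character vectors of gene symbols. Genes
#'   are trimmed and deduplicated (case-insensitively) within each signature.
#' @return An object of class `signature_registry`: the named list, with a
#'   `classification_ready` attribute that is `TRUE` iff all eight
#'   [clearseq_signature_names()] are present.
#' @export
signature_registry <- function(signatures) {
  cs_assert(is.list(signatures) && length(signatures) > 0, "empty_input",
            "signatures must be a non-empty named list")
  nm <- names(signatures)
  cs_assert(!is.null(nm) && all(nzchar(nm)), "malformed_matrix",
            "every signature needs a name")
  cs_assert(!anyDuplicated(nm), "duplicate_identifier",
            "duplicate signature name: %s",
            paste(unique(nm[duplicated(nm)]), collapse = ", "))
  signatures <- lapply(signatures, function(g) {
    g <- trimws(as.character(g))
    g <- g[nzchar(g)]
    g[!duplicated(gene_key(g))]
  })
  empty <- nm[lengths(signatures) == 0]
  cs_assert(length(empty) == 0, "empty_signature",
            "signature(s) with empty gene list: %s",
            paste(empty, collapse = ", "))
  structure(signatures, class = "signature_registry",
            classification_ready = all(clearseq_signature_names() %in% nm))
}

#' Whether a registry carries all eight classification signatures
#' @param registry A [signature_registry()].
#' @return Logical scalar.
#' @export
classification_ready <- function(registry) {
  isTRUE(attr(registry, "classification_ready"))
}

#' @export
print.signature_registry <- function(x, ...) {
  cat(sprintf("signature_registry: %d signatures (%s)%s\n", length(x),
              paste0(names(x), " [", lengths(x), "]", collapse = ", "),
              if (classification_ready(x)) "" else " - not classification-ready"))
  invisible(x)
}

#' Construct a sample x signature score matrix
#'
#' Usually produced by [score_all()]; the constructor is exported so that
#' score matrices computed elsewhere can enter the classifier.
#'
#' @param scores Numeric matrix, samples in rows, signatures in columns,
#'   finite values, dimnames set.
#' @param aggregator `"median"` or `"mean"`.
#' @param genes_used Optional named list: per signature, the genes the score
#'   was computed over.
#' @return An object of class `signature_scores`.
#' @export
signature_scores <- function(scores, aggregator = c("median", "mean"),
                             genes_used = NULL) {
  aggregator <- match.arg(aggregator)
  cs_assert(is.matrix(scores) && is.numeric(scores), "malformed_matrix",
            "scores must be a numeric matrix (samples x signatures)")
  cs_assert(nrow(scores) >= 1 && ncol(scores) >= 1, "empty_input",
            "score matrix is empty")
  cs_assert(all(is.finite(scores)), "malformed_matrix",
            "scores must be finite")
  cs_assert(!is.null(rownames(scores)) && !is.null(colnames(scores)),
            "malformed_matrix", "score matrix needs dimnames")
  structure(list(scores = scores,
                 sample_ids = rownames(scores),
                 signature_names = colnames(scores),
                 aggregator = aggregator,
                 genes_used = genes_used),
            class = "signature_scores")
}

#' @export
print.signature_scores <- function(x, ...) {
  cat(sprintf("signature_scores: %d samples x %d signatures (%s aggregator)\n",
              nrow(x$scores), ncol(x$scores), x$aggregator))
  invisible(x)
}

#' Validate a sample metadata table
#'
#' @param meta Data frame with at least `sample_id`; optional `batch`,
#'   `known_subtype` (one of the four ccrcc labels) and `tissue`
#'   (`primary`/`metastasis`).
#' @param matrix_samples Optional sample IDs of an associated matrix; when
#'   given, the metadata must cover exactly that set.
#' @return The validated data frame (class `sample_metadata` prepended).
#' @export
sample_metadata <- function(meta, matrix_samples = NULL) {
  cs_assert(is.data.frame(meta) && nrow(meta) > 0, "empty_input",
            "metadata must be a non-empty data frame")
  cs_assert("sample_id" %in% names(meta), "malformed_matrix",
            "metadata needs a sample_id column")
  meta$sample_id <- trimws(as.character(meta$sample_id))
  cs_assert(!anyDuplicated(meta$sample_id), "duplicate_identifier",
            "duplicate sample_id in metadata")
  if ("known_subtype" %in% names(meta)) {
    bad <- setdiff(stats::na.omit(unique(meta$known_subtype)), clearseq_subtypes())
    cs_assert(length(bad) == 0, "invalid_parameter",
              "unknown subtype label(s): %s", paste(bad, collapse = ", "))
  }
  if (!is.null(matrix_samples)) {
    cs_assert(setequal(meta$sample_id, matrix_samples), "sample_mismatch",
              "metadata sample set does not match the matrix")
  }
  class(meta) <- unique(c("sample_metadata", class(meta)))
  meta
}
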