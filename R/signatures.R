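#' Score one gene signature across samples
#'
#' The per-sample score is the median (bulk convention) or mean (single-cell
#' convention) of the expression of the signature genes present in the
#' matrix. Gene symbols are matched case-insensitively after trimming. At
#' least `min_fraction` of the signature's genes must be present; the score
#' is computed over the present genes only. Even-count medians use the
#' midpoint of the two central order statistics.
#'
#' @param expr An [expression_matrix()].
#' @param sig Character vector of gene symbols, or a single-element slice of
#'   a [signature_registry()].
#' @param aggregator `"median"` or `"mean"`.
#' @param min_fraction Minimum fraction of signature genes that must be
#'   present (default 0.5).
#' @return Numeric per-sample score vector (named by sample ID) with
#'   attribute `genes_used` (matrix gene IDs actually aggregated).
#' @export
score_signature <- function(expr, sig, aggregator = c("median", "mean"),
                            min_fraction = 0.5) {
  stopifnot(inherits(expr, "expression_matrix"))
  aggregator <- match.arg(aggregator)
  genes <- trimws(as.character(unlist(sig, use.names = FALSE)))
  genes <- genes[!duplicated(gene_key(genes))]
  cs_assert(length(genes) > 0, "empty_signature", "empty gene list")
  idx <- match(gene_key(genes), gene_key(rownames(expr$values)))
  present <- !is.na(idx)
  if (mean(present) < min_fraction) {
    cs_stop("insufficient_coverage",
            "only %d/%d signature genes present (min fraction %.2f); missing: %s",
            sum(present), length(genes), min_fraction,
            paste(genes[!present], collapse = ", "))
  }
  sub <- expr$values[idx[present], , drop = FALSE]
  agg <- if (aggregator == "median") stats::median else mean
  out <- apply(sub, 2, agg)
  attr(out, "genes_used") <- rownames(expr$values)[idx[present]]
  out
}

#' Score all eight classification signatures
#'
#' @param expr An [expression_matrix()].
#' @param registry A classification-ready [signature_registry()] (all eight
#'   [clearseq_signature_names()] present).
#' @param aggregator `"median"` (bulk) or `"mean"` (single-cell mode).
#' @param min_fraction Per-signature coverage requirement, see
#'   [score_signature()].
#' @return A [signature_scores()] matrix, samples x eight signatures, in the
#'   fixed column order of [clearseq_signature_names()].
#' @export
score_all <- function(expr, registry, aggregator = c("median", "mean"),
                      min_fraction = 0.5) {
  stopifnot(inherits(expr, "expression_matrix"),
            inherits(registry, "signature_registry"))
  aggregator <- match.arg(aggregator)
  need <- clearseq_signature_names()
  missing <- setdiff(need, names(registry))
  cs_assert(length(missing) == 0, "missing_signature",
            "registry is not classification-ready; missing: %s",
            paste(missing, collapse = ", "))
  genes_used <- vector("list", length(need))
  names(genes_used) <- need
  scores <- vapply(need, function(nm) {
    v <- tryCatch(score_signature(expr, registry[[nm]], aggregator, min_fraction),
                  clearseq_insufficient_coverage = function(e) {
                    cs_stop("insufficient_coverage", "signature %s: %s",
                            nm, conditionMessage(e))
                  })
    genes_used[[nm]] <<- attr(v, "genes_used")
    as.numeric(v)
  }, numeric(ncol(expr$values)))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1, dimnames = list(NULL, need))
  rownames(scores) <- expr$sample_ids
  signature_scores(scores, aggregator = aggregator, genes_used = genes_used)
}

#' Elementwise ratio of two signature score columns
#'
#' Ratios are taken on the variance-stabilized scale, as the decision rules
#' prescribe. Nonpositive denominators are an error rather than silently
#' switching to differences: they usually indicate that the matrix is on a
#' centered rather than a log-normalized-count scale.
#'
#' @param scores A [signature_scores()] object.
#' @param numerator,denominator Signature names.
#' @return Per-sample numeric ratio vector, named by sample ID.
#' @export
signature_ratio <- function(scores, numerator, denominator) {
  stopifnot(inherits(scores, "signature_scores"))
  cs_assert(all(c(numerator, denominator) %in% scores$signature_names),
            "missing_signature", "signature(s) not in score matrix")
  den <- scores$scores[, denominator]
  cs_assert(all(den > 0), "nonpositive_denominator",
            "nonpositive %s score(s); check that expression is on a log-normalized (not centered) scale",
            denominator)
  stats::setNames(scores$scores[, numerator] / den, scores$sample_ids)
}
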