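#' Filter genes by counts-per-million prevalence
#'
#' A gene is retained when its CPM (count x 1e6 / sample library size,
#' library sizes computed over all genes before any filtering) is strictly
#' above `cpm_threshold` in at least `min_samples` samples. The defaults
#' (1 CPM in >= 50 samples) are the published values for a ~600-sample
#' cohort and should be scaled for small cohorts.
#'
#' @param counts A [count_matrix()].
#' @param cpm_threshold CPM cutoff (strict `>`).
#' @param min_samples Minimum number of samples above the cutoff.
#' @return Logical gene mask, named by gene ID.
#' @export
filter_genes_cpm <- function(counts, cpm_threshold = 1, min_samples = 50) {
  stopifnot(inherits(counts, "count_matrix"))
  n <- ncol(counts$counts)
  cs_assert(min_samples <= n, "invalid_parameter",
            "min_samples (%d) exceeds the number of samples (%d)",
            min_samples, n)
  cs_assert(cpm_threshold >= 0 && min_samples >= 1, "invalid_parameter",
            "cpm_threshold must be >= 0 and min_samples >= 1")
  totals <- colSums(counts$counts)
  cs_assert(all(totals > 0), "invalid_parameter",
            "sample(s) with zero total counts: %s",
            paste(counts$sample_ids[totals == 0], collapse = ", "))
  cpm <- sweep(counts$counts, 2, totals, "/") * 1e6
  mask <- rowSums(cpm > cpm_threshold) >= min_samples
  stats::setNames(mask, counts$gene_ids)
}

#' Filter samples by sequencing depth over retained genes
#'
#' A sample is kept when the sum of its counts over the retained genes is
#' strictly greater than `min_total` (default 500,000, the published
#' boundary: a sum of exactly 500,000 is dropped).
#'
#' @param counts A [count_matrix()].
#' @param retained_genes Logical gene mask, as from [filter_genes_cpm()].
#' @param min_total Depth threshold (strict `>`).
#' @return Logical sample mask, named by sample ID.
#' @export
filter_samples_depth <- function(counts, retained_genes, min_total = 500000) {
  stopifnot(inherits(counts, "count_matrix"))
  cs_assert(length(retained_genes) == nrow(counts$counts), "invalid_parameter",
            "gene mask length (%d) does not match gene count (%d)",
            length(retained_genes), nrow(counts$counts))
  sums <- colSums(counts$counts[retained_genes, , drop = FALSE])
  mask <- sums > min_total
  if (!any(mask)) {
    warning("all samples fall below the depth threshold of ", min_total)
    cs_stop("empty_after_filter",
            "no sample has more than %s counts over retained genes",
            format(min_total, big.mark = ","))
  }
  stats::setNames(mask, counts$sample_ids)
}

#' Median-of-ratios size factors
#'
#' The standard RNA-seq normalization: the per-gene reference is the
#' geometric mean across samples over genes with all-positive counts; each
#' sample's size factor is the median over those genes of count/reference.
#'
#' @param counts A [count_matrix()].
#' @return Positive numeric vector of size factors, named by sample ID.
#' @export
size_factors_median_of_ratios <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  m <- counts$counts
  log_geo <- rowMeans(log(m))
  ok <- is.finite(log_geo)   # genes with all-positive counts
  cs_assert(any(ok), "degenerate_reference",
            "no gene has positive counts in every sample")
  sf <- apply(m, 2, function(col) {
    exp(stats::median(log(col[ok]) - log_geo[ok]))
  })
  stats::setNames(sf, counts$sample_ids)
}

#' Variance-stabilizing transform of normalized counts
#'
#' The default transform is `log2(count / size_factor + 1)`: monotone in
#' the count within a sample, zero at count zero, and invariant to jointly
#' scaling a sample's counts and its size factor. The transform name is
#' recorded so a closed-form dispersion-based VST can be slotted in.
#'
#' @param counts A [count_matrix()].
#' @param size_factors Positive per-sample factors; computed with
#'   [size_factors_median_of_ratios()] when omitted.
#' @param batch Optional per-sample batch labels carried on the result.
#' @return An [expression_matrix()] with `transform = "log2_norm_plus1"`.
#' @export
vst <- function(counts, size_factors = NULL, batch = NULL) {
  stopifnot(inherits(counts, "count_matrix"))
  if (is.null(size_factors)) size_factors <- size_factors_median_of_ratios(counts)
  cs_assert(length(size_factors) == ncol(counts$counts) && all(size_factors > 0),
            "invalid_parameter", "size factors must be positive, one per sample")
  vals <- log2(sweep(counts$counts, 2, size_factors, "/") + 1)
  expression_matrix(vals, size_factors = size_factors,
                    transform = "log2_norm_plus1", batch = batch)
}

#' Full preprocessing pipeline: filter, normalize, batch-correct
#'
#' Applies the published order of operations: CPM gene filter, depth sample
#' filter, median-of-ratios size factors, variance-stabilizing transform,
#' then empirical-Bayes batch correction when metadata with >= 2 batches is
#' supplied. Filters are computed on the merged cohort.
#'
#' @param counts A [count_matrix()].
#' @param metadata Optional [sample_metadata()] with a `batch` column.
#' @param cpm_threshold,min_samples,min_total Filter settings (see
#'   [filter_genes_cpm()], [filter_samples_depth()]).
#' @param batch_correct Apply batch correction (default: yes when metadata
#'   has >= 2 batch levels among retained samples).
#' @return An [expression_matrix()].
#' @export
preprocess_counts <- function(counts, metadata = NULL, cpm_threshold = 1,
                              min_samples = 50, min_total = 500000,
                              batch_correct = NULL) {
  gene_mask <- filter_genes_cpm(counts, cpm_threshold, min_samples)
  cs_assert(any(gene_mask), "empty_after_filter",
            "no gene passes the CPM filter")
  sample_mask <- filter_samples_depth(counts, gene_mask, min_total)
  kept <- count_matrix(counts$counts[gene_mask, sample_mask, drop = FALSE])
  batch <- NULL
  if (!is.null(metadata) && "batch" %in% names(metadata)) {
    idx <- match(kept$sample_ids, metadata$sample_id)
    cs_assert(!anyNA(idx), "sample_mismatch",
              "metadata is missing sample(s): %s",
              paste(kept$sample_ids[is.na(idx)], collapse = ", "))
    batch <- as.character(metadata$batch[idx])
    cs_assert(all(nzchar(batch)), "invalid_parameter",
              "empty batch label(s) in metadata")
  }
  expr <- vst(kept, batch = batch)
  if (is.null(batch_correct)) {
    batch_correct <- !is.null(batch) && length(unique(batch)) >= 2
  }
  if (batch_correct) {
    cs_assert(!is.null(batch), "invalid_parameter",
              "batch correction requested but metadata has no batch column")
    expr <- combat(expr, batch)
  }
  expr
}
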