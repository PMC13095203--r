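#' Read a gene x sample count matrix
#'
#' TSV/CSV files must have a header row of sample IDs and gene IDs in the
#' first column. The MatrixMarket triplet dialect reads a `.mtx` file plus
#' two plain-text companion files with one gene / sample name per line
#' (1-based indices, per the MatrixMarket convention).
#'
#' @param path Path to the matrix file.
#' @param dialect One of `"tsv"`, `"csv"`, `"mtx_triplet"`.
#' @param genes_file,samples_file Companion name files for `mtx_triplet`;
#'   default `<path without .mtx>.genes.txt` / `.samples.txt`.
#' @return A validated [count_matrix()].
#' @export
read_count_matrix <- function(path, dialect = c("tsv", "csv", "mtx_triplet"),
                              genes_file = NULL, samples_file = NULL) {
  dialect <- match.arg(dialect)
  cs_assert(file.exists(path), "io_failure", "file not found: %s", path)
  if (dialect == "mtx_triplet") {
    stem <- sub("\\.mtx$", "", path)
    if (is.null(genes_file)) genes_file <- paste0(stem, ".genes.txt")
    if (is.null(samples_file)) samples_file <- paste0(stem, ".samples.txt")
    cs_assert(file.exists(genes_file) && file.exists(samples_file),
              "io_failure", "companion row/column name files not found for %s", path)
    m <- as.matrix(Matrix::readMM(path))
    genes <- trimws(readLines(genes_file))
    samples <- trimws(readLines(samples_file))
    cs_assert(length(genes) == nrow(m) && length(samples) == ncol(m),
              "malformed_matrix",
              "name files do not match matrix dimensions (%d x %d)", nrow(m), ncol(m))
    dimnames(m) <- list(genes, samples)
    return(count_matrix(m))
  }
  sep <- if (dialect == "tsv") "\t" else ","
  raw <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "")
  cs_assert(nrow(raw) >= 1 && ncol(raw) >= 2, "empty_input",
            "no data rows/columns in %s", path)
  genes <- trimws(raw[[1]])
  cs_assert(!anyDuplicated(genes), "duplicate_identifier",
            "duplicate gene IDs in %s: %s", path,
            paste(unique(genes[duplicated(genes)]), collapse = ", "))
  vals <- as.matrix(raw[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- is.na(num) & !is.na(vals)
  cs_assert(!any(bad), "malformed_matrix",
            "non-numeric cell(s) in %s (e.g. gene %s)", path,
            genes[which(rowSums(bad) > 0)[1]])
  cs_assert(!anyNA(num), "malformed_matrix", "missing values in %s", path)
  dimnames(num) <- list(genes, colnames(vals))
  count_matrix(num)
}

#' Write a count matrix as TSV/CSV
#' @param x A [count_matrix()].
#' @param path Output path.
#' @param dialect `"tsv"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(x, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(x, "count_matrix"))
  df <- data.frame(gene_id = x$gene_ids, x$counts, check.names = FALSE)
  write_table_checked(df, path, sep = if (dialect == "tsv") "\t" else ",")
}

#' Read gene signature definitions
#'
#' GMT lines are `name<TAB>description<TAB>gene1<TAB>gene2...`; the
#' two-column dialect is a TSV with columns signature name and gene symbol
#' (an optional header line `signature<TAB>gene` is skipped).
#'
#' @param path Path to the definitions file.
#' @param format `"gmt"` or `"two_column_tsv"`.
#' @return A [signature_registry()].
#' @export
read_signatures <- function(path, format = c("gmt", "two_column_tsv")) {
  format <- match.arg(format)
  cs_assert(file.exists(path), "io_failure", "file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  cs_assert(length(lines) > 0, "empty_input", "no signatures in %s", path)
  if (format == "gmt") {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nm <- vapply(parts, function(p) trimws(p[1]), character(1))
    genes <- lapply(parts, function(p) if (length(p) > 2) p[-(1:2)] else character(0))
  } else {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    cs_assert(all(lengths(parts) >= 2), "malformed_matrix",
              "two-column signature file needs 2 columns per row")
    sig <- vapply(parts, function(p) trimws(p[1]), character(1))
    gene <- vapply(parts, function(p) trimws(p[2]), character(1))
    if (tolower(sig[1]) %in% c("signature", "name") && tolower(gene[1]) == "gene") {
      sig <- sig[-1]; gene <- gene[-1]
    }
    nm <- unique(sig)
    genes <- lapply(nm, function(s) gene[sig == s])
  }
  cs_assert(!anyDuplicated(nm), "duplicate_identifier",
            "duplicate signature name in %s: %s", path,
            paste(unique(nm[duplicated(nm)]), collapse = ", "))
  signature_registry(stats::setNames(genes, nm))
}

#' Write a signature registry in GMT format
#' @param registry A [signature_registry()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signatures <- function(registry, path) {
  stopifnot(inherits(registry, "signature_registry"))
  lines <- vapply(names(registry), function(nm) {
    paste(c(nm, "clearseq", registry[[nm]]), collapse = "\t")
  }, character(1))
  ok <- tryCatch({ writeLines(lines, path); TRUE }, error = function(e) FALSE)
  cs_assert(ok, "io_failure", "cannot write %s", path)
  invisible(path)
}

#' Read a sample metadata table (TSV with header)
#' @param path Path to a TSV with at least a `sample_id` column.
#' @return A validated [sample_metadata()] data frame.
#' @export
read_sample_metadata <- function(path) {
  cs_assert(file.exists(path), "io_failure", "file not found: %s", path)
  meta <- utils::read.table(path, sep = "\t", header = TRUE,
                            check.names = FALSE, colClasses = "character")
  sample_metadata(meta)
}

#' Write classification results as TSV
#'
#' One row per sample: label, the six decision statistics, the eight
#' signature scores, the realized cutoffs (constant across rows) and the
#' compact rule trace. [read_classification()] reproduces the label vector
#' exactly.
#'
#' @param calls A `cohort_classification` from [classify_cohort()] /
#'   [classify_fixed()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_classification <- function(calls, path) {
  stopifnot(inherits(calls, "cohort_classification"))
  cs_assert(nrow(calls$calls) > 0, "empty_input", "no calls to write")
  df <- calls$calls
  for (nm in names(calls$cutoffs)) df[[paste0("cutoff_", nm)]] <- calls$cutoffs[[nm]]
  write_table_checked(df, path, sep = "\t")
}

#' Read back a classification TSV
#' @param path Path written by [write_classification()].
#' @return Data frame with at least `sample_id` and `subtype`.
#' @export
read_classification <- function(path) {
  cs_assert(file.exists(path), "io_failure", "file not found: %s", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          colClasses = "character")
  cs_assert(all(c("sample_id", "subtype") %in% names(df)), "malformed_matrix",
            "not a classification table: %s", path)
  num <- setdiff(names(df), c("sample_id", "subtype", "rule_trace"))
  for (nm in num) df[[nm]] <- as.numeric(df[[nm]])
  df
}

#' Write an expression matrix as TSV
#' @param x An [expression_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "expression_matrix"))
  df <- data.frame(gene_id = x$gene_ids, x$values, check.names = FALSE)
  write_table_checked(df, path, sep = "\t")
}

#' Read an already-normalized expression matrix from TSV
#'
#' The values are taken as-is (`transform = "precomputed"`); use this to
#' feed externally normalized data into scoring.
#'
#' @param path TSV with header row = sample IDs, first column = gene IDs.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path) {
  cs_assert(file.exists(path), "io_failure", "file not found: %s", path)
  raw <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  genes <- trimws(as.character(raw[[1]]))
  cs_assert(!anyDuplicated(genes), "duplicate_identifier",
            "duplicate gene IDs in %s", path)
  vals <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  cs_assert(!anyNA(vals), "malformed_matrix", "missing values in %s", path)
  rownames(vals) <- genes
  expression_matrix(vals, transform = "precomputed")
}

#' Write a score matrix as TSV
#' @param x A [signature_scores()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(x, path) {
  stopifnot(inherits(x, "signature_scores"))
  df <- data.frame(sample_id = x$sample_ids, x$scores, check.names = FALSE)
  write_table_checked(df, path, sep = "\t")
}

#' Read a score matrix from TSV
#' @param path TSV written by [write_scores()].
#' @param aggregator Aggregator recorded on the object.
#' @return A [signature_scores()] object.
#' @export
read_scores <- function(path, aggregator = "median") {
  cs_assert(file.exists(path), "io_failure", "file not found: %s", path)
  raw <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(raw[[1]])
  signature_scores(m, aggregator = aggregator)
}

write_table_checked <- function(df, path, sep) {
  ok <- tryCatch({
    utils::write.table(df, path, sep = sep, quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  cs_assert(ok, "io_failure", "cannot write %s", path)
  invisible(path)
}
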