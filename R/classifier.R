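#' Linear-interpolation percentile
#'
#' The convention shared by every decision rule: on the sorted values the
#' k-th of n sits at percent 100*(k-1)/(n-1) and intermediate percents are
#' linearly interpolated (R's default quantile type 7).
#'
#' @param values Non-empty numeric vector of finite values.
#' @param q Percent in (0, 100].
#' @return The interpolated percentile value.
#' @export
percentile <- function(values, q) {
  cs_assert(length(values) > 0, "empty_input", "empty value vector")
  cs_assert(all(is.finite(values)), "invalid_parameter", "non-finite values")
  cs_assert(is.numeric(q) && length(q) == 1 && q > 0 && q <= 100,
            "invalid_parameter", "q must be a percent in (0, 100]")
  unname(stats::quantile(values, q / 100, type = 7, names = FALSE))
}

cutoff_names <- function() {
  c("p3_ratio", "p3_ccrcc2up", "p3_cellcycle", "p3_teffector",
    "p2_ratio", "p4_ratio")
}

#' Decision-tree thresholds
#'
#' The published percentile rules: ccrcc3 requires the ccrcc3_up/ccrcc3_down
#' ratio in the upper 20th percentile (i.e. above the 80th) together with
#' ccrcc2_up in the lower 50th, cell cycle in the lower 64th and T-effector
#' in the lower 75th percentile; ccrcc2 is the upper half of the
#' ccrcc2_up/ccrcc1and4_up ratio among the rest; ccrcc4 the highest 40th
#' percentile of the ccrcc4_up/ccrcc1_up ratio among the remainder.
#'
#' @param p3_ratio_pct,p3_ccrcc2up_pct,p3_cellcycle_pct,p3_teffector_pct,p2_ratio_pct,p4_ratio_pct
#'   Percentile settings; defaults are the published 80/50/64/75/50/60.
#' @param mode `"cohort_percentile"` (thresholds realized on the cohort) or
#'   `"fixed_cutoff"` (absolute score cutoffs, usable for single samples).
#' @param cutoffs Named numeric vector of the six absolute cutoffs
#'   (`r c("p3_ratio", "p3_ccrcc2up", "p3_cellcycle", "p3_teffector", "p2_ratio", "p4_ratio")`),
#'   required when `mode = "fixed_cutoff"`.
#' @return An object of class `threshold_set`.
#' @export
threshold_set <- function(p3_ratio_pct = 80, p3_ccrcc2up_pct = 50,
                          p3_cellcycle_pct = 64, p3_teffector_pct = 75,
                          p2_ratio_pct = 50, p4_ratio_pct = 60,
                          mode = c("cohort_percentile", "fixed_cutoff"),
                          cutoffs = NULL) {
  mode <- match.arg(mode)
  pct <- c(p3_ratio = p3_ratio_pct, p3_ccrcc2up = p3_ccrcc2up_pct,
           p3_cellcycle = p3_cellcycle_pct, p3_teffector = p3_teffector_pct,
           p2_ratio = p2_ratio_pct, p4_ratio = p4_ratio_pct)
  cs_assert(all(pct > 0 & pct < 100), "invalid_parameter",
            "percentiles must lie in (0, 100)")
  if (mode == "fixed_cutoff") {
    missing <- setdiff(cutoff_names(), names(cutoffs))
    cs_assert(length(missing) == 0, "incomplete_thresholds",
              "fixed-cutoff mode needs cutoff(s): %s",
              paste(missing, collapse = ", "))
    cutoffs <- cutoffs[cutoff_names()]
    cs_assert(all(is.finite(cutoffs)), "incomplete_thresholds",
              "fixed cutoffs must be finite")
  }
  structure(list(percentiles = pct, mode = mode, cutoffs = cutoffs),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf("threshold_set [%s]: %s\n", x$mode,
              paste(names(x$percentiles), x$percentiles, sep = "=",
                    collapse = ", ")))
  if (!is.null(x$cutoffs)) {
    cat("  cutoffs:", paste(names(x$cutoffs), signif(x$cutoffs, 5), sep = "=",
                            collapse = ", "), "\n")
  }
  invisible(x)
}

# The six per-sample decision statistics, in rule order.
decision_statistics <- function(scores) {
  stopifnot(inherits(scores, "signature_scores"))
  missing <- setdiff(clearseq_signature_names(), scores$signature_names)
  cs_assert(length(missing) == 0, "missing_signature",
            "score matrix is missing signature(s): %s",
            paste(missing, collapse = ", "))
  data.frame(
    sample_id = scores$sample_ids,
    stat_ccrcc3_ratio = as.numeric(signature_ratio(scores, "ccrcc3_up", "ccrcc3_down")),
    stat_ccrcc2_up = unname(scores$scores[, "ccrcc2_up"]),
    stat_cell_cycle = unname(scores$scores[, "cell_cycle"]),
    stat_t_effector = unname(scores$scores[, "t_effector"]),
    stat_ccrcc2_ratio = as.numeric(signature_ratio(scores, "ccrcc2_up", "ccrcc1and4_up")),
    stat_ccrcc4_ratio = as.numeric(signature_ratio(scores, "ccrcc4_up", "ccrcc1_up")),
    stringsAsFactors = FALSE)
}

# Shared four-step tree given the six absolute cutoffs.
apply_tree <- function(stats_df, cut) {
  n <- nrow(stats_df)
  lab <- rep(NA_character_, n)
  trace <- character(n)
  c1 <- stats_df$stat_ccrcc3_ratio > cut[["p3_ratio"]]
  c2 <- stats_df$stat_ccrcc2_up <= cut[["p3_ccrcc2up"]]
  c3 <- stats_df$stat_cell_cycle <= cut[["p3_cellcycle"]]
  c4 <- stats_df$stat_t_effector <= cut[["p3_teffector"]]
  is3 <- c1 & c2 & c3 & c4
  lab[is3] <- "ccrcc3"
  s1 <- paste0("s1=", ifelse(c1, "T", "F"), ifelse(c2, "T", "F"),
               ifelse(c3, "T", "F"), ifelse(c4, "T", "F"))
  is2 <- !is3 & stats_df$stat_ccrcc2_ratio > cut[["p2_ratio"]]
  lab[is2] <- "ccrcc2"
  is4 <- !is3 & !is2 & stats_df$stat_ccrcc4_ratio > cut[["p4_ratio"]]
  lab[is4] <- "ccrcc4"
  lab[is.na(lab)] <- "ccrcc1"
  trace <- ifelse(is3, paste0(s1, ">ccrcc3"),
           ifelse(is2, paste0(s1, ";s2=T>ccrcc2"),
           ifelse(is4, paste0(s1, ";s2=F;s3=T>ccrcc4"),
                       paste0(s1, ";s2=F;s3=F>ccrcc1"))))
  list(label = lab, trace = trace)
}

build_classification <- function(scores, stats_df, cut, thresholds, mode) {
  res <- apply_tree(stats_df, cut)
  calls <- cbind(
    data.frame(sample_id = stats_df$sample_id,
               subtype = res$label, stringsAsFactors = FALSE),
    stats_df[setdiff(names(stats_df), "sample_id")],
    stats::setNames(as.data.frame(scores$scores),
                    paste0("score_", colnames(scores$scores))))
  calls$rule_trace <- res$trace
  rownames(calls) <- NULL
  counts <- table(factor(res$label, levels = clearseq_subtypes()))
  structure(list(calls = calls,
                 cutoffs = cut,
                 class_counts = stats::setNames(as.integer(counts),
                                                clearseq_subtypes()),
                 thresholds = thresholds,
                 mode = mode),
            class = "cohort_classification")
}

#' Classify a cohort with cohort-realized percentile cutoffs
#'
#' The four-step decision tree. Step 1 computes the four ccrcc3 criteria
#' against percentiles over *all* samples and labels samples meeting all
#' four as ccrcc3. Step 2 computes the 50th percentile of the
#' ccrcc2_up/ccrcc1and4_up ratio over the *non-ccrcc3* samples; samples
#' strictly above it become ccrcc2. Step 3 computes the 60th percentile of
#' the ccrcc4_up/ccrcc1_up ratio over the still-unlabeled samples; samples
#' strictly above it become ccrcc4. Step 4 labels the remainder ccrcc1.
#' "Upper" criteria are strict `>`; "lower" criteria are inclusive `<=`.
#'
#' @param scores A [signature_scores()] matrix with all eight signatures.
#' @param thresholds A cohort-mode [threshold_set()].
#' @param min_cohort Minimum cohort size for percentile mode (default 20);
#'   use [classify_fixed()] below it.
#' @return An object of class `cohort_classification`: per-sample calls with
#'   decision statistics and rule traces, the six realized cutoffs, and
#'   class counts.
#' @export
classify_cohort <- function(scores, thresholds = threshold_set(),
                            min_cohort = 20) {
  stopifnot(inherits(scores, "signature_scores"),
            inherits(thresholds, "threshold_set"))
  cs_assert(thresholds$mode == "cohort_percentile", "invalid_parameter",
            "thresholds are in fixed-cutoff mode; call classify_fixed()")
  n <- nrow(scores$scores)
  cs_assert(n >= min_cohort, "cohort_too_small",
            "cohort mode needs >= %d samples (got %d); use fixed-cutoff mode for small datasets or single samples",
            min_cohort, n)
  st <- decision_statistics(scores)
  pct <- thresholds$percentiles
  cut <- c(p3_ratio = percentile(st$stat_ccrcc3_ratio, pct[["p3_ratio"]]),
           p3_ccrcc2up = percentile(st$stat_ccrcc2_up, pct[["p3_ccrcc2up"]]),
           p3_cellcycle = percentile(st$stat_cell_cycle, pct[["p3_cellcycle"]]),
           p3_teffector = percentile(st$stat_t_effector, pct[["p3_teffector"]]),
           p2_ratio = NA_real_, p4_ratio = NA_real_)
  is3 <- st$stat_ccrcc3_ratio > cut[["p3_ratio"]] &
    st$stat_ccrcc2_up <= cut[["p3_ccrcc2up"]] &
    st$stat_cell_cycle <= cut[["p3_cellcycle"]] &
    st$stat_t_effector <= cut[["p3_teffector"]]
  rem2 <- !is3
  cs_assert(any(rem2), "empty_after_filter", "every sample classified ccrcc3")
  cut[["p2_ratio"]] <- percentile(st$stat_ccrcc2_ratio[rem2], pct[["p2_ratio"]])
  is2 <- rem2 & st$stat_ccrcc2_ratio > cut[["p2_ratio"]]
  rem3 <- rem2 & !is2
  cs_assert(any(rem3), "empty_after_filter",
            "no samples left for the ccrcc4/ccrcc1 split")
  cut[["p4_ratio"]] <- percentile(st$stat_ccrcc4_ratio[rem3], pct[["p4_ratio"]])
  build_classification(scores, st, cut, thresholds, "cohort_percentile")
}

#' Classify with fixed absolute cutoffs
#'
#' The same four-step logic with absolute score cutoffs replacing cohort
#' percentiles; valid for any number of samples, including one. Cutoffs are
#' typically extracted from a reference cohort with [extract_cutoffs()] and
#' are only meaningful when preprocessing closely matches that cohort's.
#'
#' @param scores A [signature_scores()] matrix.
#' @param thresholds A fixed-cutoff [threshold_set()] with all six values.
#' @return A `cohort_classification`.
#' @export
classify_fixed <- function(scores, thresholds) {
  stopifnot(inherits(scores, "signature_scores"),
            inherits(thresholds, "threshold_set"))
  cs_assert(thresholds$mode == "fixed_cutoff", "incomplete_thresholds",
            "thresholds must be in fixed-cutoff mode with all six cutoffs")
  st <- decision_statistics(scores)
  build_classification(scores, st, thresholds$cutoffs[cutoff_names()],
                       thresholds, "fixed_cutoff")
}

#' Package the realized cutoffs of a cohort classification for reuse
#'
#' @param classification A `cohort_classification` produced in cohort mode.
#' @return A fixed-cutoff [threshold_set()]; applying it back to the same
#'   cohort with [classify_fixed()] reproduces the labels exactly.
#' @export
extract_cutoffs <- function(classification) {
  stopifnot(inherits(classification, "cohort_classification"))
  cs_assert(classification$mode == "cohort_percentile", "invalid_parameter",
            "cutoffs can only be extracted from a cohort-mode classification")
  p <- classification$thresholds$percentiles
  threshold_set(p3_ratio_pct = p[["p3_ratio"]],
                p3_ccrcc2up_pct = p[["p3_ccrcc2up"]],
                p3_cellcycle_pct = p[["p3_cellcycle"]],
                p3_teffector_pct = p[["p3_teffector"]],
                p2_ratio_pct = p[["p2_ratio"]],
                p4_ratio_pct = p[["p4_ratio"]],
                mode = "fixed_cutoff",
                cutoffs = classification$cutoffs)
}

#' Serialize thresholds to JSON
#' @param thresholds A [threshold_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_thresholds <- function(thresholds, path) {
  stopifnot(inherits(thresholds, "threshold_set"))
  obj <- list(mode = thresholds$mode,
              percentiles = as.list(thresholds$percentiles),
              cutoffs = if (is.null(thresholds$cutoffs)) NULL else
                as.list(thresholds$cutoffs))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

#' Read thresholds from JSON
#' @param path Path written by [write_thresholds()].
#' @return A [threshold_set()].
#' @export
read_thresholds <- function(path) {
  cs_assert(file.exists(path), "io_failure", "file not found: %s", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- obj$percentiles
  threshold_set(p3_ratio_pct = p$p3_ratio, p3_ccrcc2up_pct = p$p3_ccrcc2up,
                p3_cellcycle_pct = p$p3_cellcycle,
                p3_teffector_pct = p$p3_teffector,
                p2_ratio_pct = p$p2_ratio, p4_ratio_pct = p$p4_ratio,
                mode = obj$mode,
                cutoffs = if (is.null(obj$cutoffs)) NULL else unlist(obj$cutoffs))
}

#' @export
print.cohort_classification <- function(x, ...) {
  cat(sprintf("cohort_classification [%s]: n = %d\n", x$mode,
              sum(x$class_counts)))
  print(x$class_counts)
  cat("cutoffs:", paste(names(x$cutoffs), signif(x$cutoffs, 5), sep = "=",
                        collapse = ", "), "\n")
  invisible(x)
}

#' Cross-tabulate two label vectors with row percentages
#'
#' @param labels_a,labels_b Subtype label vectors over the same samples;
#'   when both are named, they are aligned by name.
#' @param levels Label universe (default the four ccrcc subtypes).
#' @return An object of class `confusion_table` with integer `counts`, the
#'   `row_pct` matrix (100 x count / row total, rounded to integers for
#'   display, zero rows reported as 0) and row totals.
#' @export
concordance <- function(labels_a, labels_b, levels = clearseq_subtypes()) {
  if (!is.null(names(labels_a)) && !is.null(names(labels_b))) {
    cs_assert(setequal(names(labels_a), names(labels_b)), "sample_mismatch",
              "label vectors cover different sample sets")
    labels_b <- labels_b[names(labels_a)]
  } else {
    cs_assert(length(labels_a) == length(labels_b), "sample_mismatch",
              "label vectors differ in length")
  }
  cs_assert(!anyNA(labels_a) && !anyNA(labels_b), "invalid_parameter",
            "labels must be fully assigned")
  bad <- setdiff(unique(c(labels_a, labels_b)), levels)
  cs_assert(length(bad) == 0, "invalid_parameter",
            "label(s) outside the level set: %s", paste(bad, collapse = ", "))
  counts <- table(factor(labels_a, levels = levels),
                  factor(labels_b, levels = levels))
  counts <- matrix(as.integer(counts), nrow = length(levels),
                   dimnames = list(A = levels, B = levels))
  totals <- as.integer(rowSums(counts))
  names(totals) <- levels
  pct <- counts
  pct[] <- 0L
  nz <- totals > 0
  # half-up rounding (62.5 -> 63), matching conventional table display
  pct[nz, ] <- floor(100 * counts[nz, , drop = FALSE] / totals[nz] + 0.5)
  structure(list(counts = counts, row_pct = pct, row_totals = totals),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  disp <- matrix(sprintf("%d (%d%%)", x$counts, x$row_pct),
                 nrow = nrow(x$counts), dimnames = dimnames(x$counts))
  print(cbind(n = x$row_totals, as.data.frame(disp)))
  invisible(x)
}
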