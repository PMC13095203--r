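# Synthetic cohorts with planted four-subtype and batch structure. The
# generator states a world matching the classifier's design: subtype
# proportions default to the proportions the percentile tree itself induces
# (20% ccrcc3; 50% of the rest ccrcc2; 40% of the remainder ccrcc4), so
# that at large effect sizes the tree can recover the planted truth.

subtype_archetypes <- function() {
  # rows: subtypes; cols: signatures; entries multiply the effect size on
  # the log2 scale. ccrcc3 is the "normal kidney-like" archetype: low
  # angiogenesis, cell-cycle and T-effector programs, high up/down ratio.
  a <- matrix(0, 4, 8, dimnames = list(clearseq_subtypes(),
                                       clearseq_signature_names()))
  a["ccrcc1", c("ccrcc1_up", "ccrcc1and4_up")] <- 1
  a["ccrcc2", "ccrcc2_up"] <- 1
  a["ccrcc3", "ccrcc3_up"] <- 1
  a["ccrcc3", c("ccrcc3_down", "ccrcc2_up", "cell_cycle", "t_effector")] <- -0.5
  a["ccrcc4", c("ccrcc4_up", "t_effector")] <- 1
  a["ccrcc4", "ccrcc1and4_up"] <- 1
  a
}

# Deterministic class sizes by largest remainder, then a seeded shuffle.
allocate_subtypes <- function(n, proportions) {
  base <- floor(n * proportions)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- n * proportions - base
    base[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
      base[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1
  }
  sample(rep(names(proportions), base))
}

#' Simulation settings for planted-structure count cohorts
#'
#' @param n_samples Cohort size.
#' @param subtype_proportions Named nonnegative vector over the four
#'   subtypes summing to 1. Default `c(0.24, 0.40, 0.20, 0.16)` — the
#'   distribution the percentile tree induces when ccrcc3 fills its 20%
#'   quota.
#' @param n_background_genes Genes with no subtype effect.
#' @param genes_per_signature Planted genes per signature.
#' @param effect_size Per-subtype shift on that subtype's defining
#'   signature genes, in within-class SD units of the log2 expression.
#' @param nb_dispersion Negative-binomial dispersion phi
#'   (variance = mu + mu^2 phi).
#' @param base_mean_range Range of per-gene base means (log-uniform).
#' @param batch_labels Optional batch label per sample (or a named
#'   proportion vector, e.g. `c(A = 0.5, B = 0.5)`).
#' @param batch_fold_effects Named multiplicative fold per batch (fold 1 =
#'   reference). Each gene gets the fold or its reciprocal with equal
#'   probability, so batches differ per gene without a pure library-size
#'   shift.
#' @param seed Mandatory integer seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples = 670,
                           subtype_proportions = c(ccrcc1 = 0.24, ccrcc2 = 0.40,
                                                   ccrcc3 = 0.20, ccrcc4 = 0.16),
                           n_background_genes = 300,
                           genes_per_signature = 6,
                           effect_size = 4,
                           nb_dispersion = 0.1,
                           base_mean_range = c(100, 1000),
                           batch_labels = NULL,
                           batch_fold_effects = NULL,
                           seed) {
  cs_assert(!missing(seed) && is.finite(seed), "invalid_parameter",
            "a seed is mandatory")
  cs_assert(n_samples >= 1, "invalid_parameter", "n_samples must be >= 1")
  cs_assert(setequal(names(subtype_proportions), clearseq_subtypes()),
            "invalid_parameter", "proportions must be named by the four subtypes")
  subtype_proportions <- subtype_proportions[clearseq_subtypes()]
  cs_assert(all(subtype_proportions >= 0) &&
              abs(sum(subtype_proportions) - 1) < 1e-9, "invalid_parameter",
            "subtype proportions must be nonnegative and sum to 1")
  cs_assert(effect_size >= 0, "invalid_parameter", "effect_size must be >= 0")
  cs_assert(nb_dispersion > 0, "invalid_parameter", "nb_dispersion must be > 0")
  cs_assert(length(base_mean_range) == 2 && all(base_mean_range > 0) &&
              diff(base_mean_range) >= 0, "invalid_parameter",
            "invalid base_mean_range")
  if (!is.null(batch_labels) && length(batch_labels) != n_samples) {
    cs_assert(!is.null(names(batch_labels)) &&
                abs(sum(batch_labels) - 1) < 1e-9, "invalid_parameter",
              "batch_labels must be per-sample labels or named proportions summing to 1")
  }
  structure(list(n_samples = n_samples,
                 subtype_proportions = subtype_proportions,
                 n_background_genes = n_background_genes,
                 genes_per_signature = genes_per_signature,
                 effect_size = effect_size,
                 nb_dispersion = nb_dispersion,
                 base_mean_range = base_mean_range,
                 batch_labels = batch_labels,
                 batch_fold_effects = batch_fold_effects,
                 seed = seed),
            class = "synthetic_spec")
}

#' Simulate signature-score matrices directly
#'
#' Three structures: `tie_free_uniform` draws every score from continuous
#' uniforms (ties have probability zero); `four_centroid` places the four
#' archetype centroids `separation` within-class SDs apart on their
#' defining signatures (true labels attached as attribute `true_subtype`);
#' `adversarial_no_ccrcc3` permutes T-effector scores so that every sample
#' in the top quintile of the ccrcc3 ratio has a T-effector score above the
#' cohort's 75th percentile, guaranteeing zero ccrcc3 calls by construction.
#'
#' @param n Number of samples.
#' @param structure One of the three structures above.
#' @param params Optional list: `separation` (default 4) and `proportions`
#'   for `four_centroid`.
#' @param seed Mandatory integer seed.
#' @return A [signature_scores()] object (median aggregator); for
#'   `four_centroid`, attribute `true_subtype` carries the planted labels.
#' @export
simulate_scores <- function(n, structure = c("tie_free_uniform", "four_centroid",
                                             "adversarial_no_ccrcc3"),
                            params = list(), seed) {
  structure_ <- match.arg(structure)
  cs_assert(!missing(seed) && is.finite(seed), "invalid_parameter",
            "a seed is mandatory")
  cs_assert(n >= 1, "invalid_parameter", "n must be >= 1")
  sig <- clearseq_signature_names()
  with_local_seed(seed, {
    if (structure_ == "tie_free_uniform" || structure_ == "adversarial_no_ccrcc3") {
      m <- matrix(stats::runif(n * 8, 1, 10), nrow = n,
                  dimnames = list(sprintf("S%04d", seq_len(n)), sig))
      if (structure_ == "adversarial_no_ccrcc3" && n >= 2) {
        ratio <- m[, "ccrcc3_up"] / m[, "ccrcc3_down"]
        k <- max(1, ceiling(0.2 * n))
        top_ratio <- order(ratio, decreasing = TRUE)[seq_len(k)]
        # hand the top-k T-effector values to the top-k ratio samples
        te <- m[, "t_effector"]
        ord_te <- order(te, decreasing = TRUE)
        new_te <- te
        new_te[top_ratio] <- te[ord_te[seq_len(k)]]
        rest <- setdiff(seq_len(n), top_ratio)
        new_te[rest] <- te[ord_te[-seq_len(k)]][sample(length(rest))]
        m[, "t_effector"] <- new_te
      }
      truth <- NULL
    } else {
      separation <- if (is.null(params$separation)) 4 else params$separation
      cs_assert(separation >= 0, "invalid_parameter", "separation must be >= 0")
      proportions <- if (is.null(params$proportions)) {
        c(ccrcc1 = 0.24, ccrcc2 = 0.40, ccrcc3 = 0.20, ccrcc4 = 0.16)
      } else {
        params$proportions[clearseq_subtypes()]
      }
      cs_assert(abs(sum(proportions) - 1) < 1e-9, "invalid_parameter",
                "proportions must sum to 1")
      truth <- allocate_subtypes(n, proportions)
      centroids <- 10 + subtype_archetypes() * separation
      m <- centroids[truth, , drop = FALSE] +
        matrix(stats::rnorm(n * 8), nrow = n)
      m[m <= 0.1] <- 0.1      # keep ratio denominators positive
      dimnames(m) <- list(sprintf("S%04d", seq_len(n)), sig)
    }
    out <- signature_scores(m, aggregator = "median")
    if (!is.null(truth)) {
      attr(out, "true_subtype") <- stats::setNames(truth, rownames(m))
    }
    out
  })
}

#' Simulate a count cohort with planted subtype and batch structure
#'
#' Counts are negative binomial with per-gene base means drawn log-uniform
#' from `base_mean_range`; each subtype shifts its defining signature genes
#' by `effect_size` within-class SDs on the log2 scale (the within-class SD
#' of log2 expression for an NB gene is approximately
#' `sqrt(1/mu + phi)/ln 2`); batch effects multiply gene means by the
#' batch's fold or its reciprocal (per-gene random sign).
#'
#' @param spec A [synthetic_spec()].
#' @return An object of class `synthetic_cohort`: `counts`
#'   ([count_matrix()]), `metadata` (sample_id, batch, true_subtype) and
#'   `registry` (a [signature_registry()] naming the planted genes).
#' @export
simulate_counts <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  sig <- clearseq_signature_names()
  with_local_seed(spec$seed, {
    n <- spec$n_samples
    truth <- allocate_subtypes(n, spec$subtype_proportions)
    sample_ids <- sprintf("S%04d", seq_len(n))

    sig_genes <- lapply(sig, function(s) {
      sprintf("%s_G%02d", toupper(gsub("_", "", s)), seq_len(spec$genes_per_signature))
    })
    names(sig_genes) <- sig
    bg <- if (spec$n_background_genes > 0) {
      sprintf("BG_%04d", seq_len(spec$n_background_genes))
    } else {
      character(0)
    }
    genes <- c(unlist(sig_genes, use.names = FALSE), bg)
    g <- length(genes)
    gene_sig <- c(rep(sig, each = spec$genes_per_signature),
                  rep(NA_character_, length(bg)))

    base_mean <- exp(stats::runif(g, log(spec$base_mean_range[1]),
                                  log(spec$base_mean_range[2])))
    sd_log2 <- sqrt(1 / base_mean + spec$nb_dispersion) / log(2)

    arch <- subtype_archetypes()
    shift <- matrix(0, g, n)                       # log2 shifts
    in_sig <- !is.na(gene_sig)
    arch_t <- t(arch[truth, , drop = FALSE])       # signatures x samples
    shift[in_sig, ] <- arch_t[gene_sig[in_sig], , drop = FALSE] *
      (spec$effect_size * sd_log2[in_sig])

    batch <- spec$batch_labels
    if (is.null(batch)) {
      batch <- rep("batch1", n)
    } else if (length(batch) != n) {
      batch <- allocate_subtypes(n, batch)         # reuse allocator for batches
    }
    batch <- as.character(batch)
    bshift <- matrix(0, g, n)
    if (!is.null(spec$batch_fold_effects)) {
      for (b in names(spec$batch_fold_effects)) {
        fold <- spec$batch_fold_effects[[b]]
        if (fold == 1) next
        sgn <- sample(c(-1, 1), g, replace = TRUE)
        bshift[, batch == b] <- sgn * log2(fold)
      }
    }

    mu <- base_mean * 2^(shift + bshift)
    counts <- matrix(stats::rnbinom(g * n, mu = mu, size = 1 / spec$nb_dispersion),
                     nrow = g, dimnames = list(genes, sample_ids))
    structure(list(counts = count_matrix(counts),
                   metadata = sample_metadata(
                     data.frame(sample_id = sample_ids, batch = batch,
                                known_subtype = truth,
                                stringsAsFactors = FALSE)),
                   registry = signature_registry(sig_genes),
                   spec = spec),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d genes x %d samples, effect %g SD, seed %s\n",
              nrow(x$counts$counts), ncol(x$counts$counts),
              x$spec$effect_size, format(x$spec$seed)))
  print(table(x$metadata$known_subtype))
  invisible(x)
}
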