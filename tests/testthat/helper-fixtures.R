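# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

# A minimal registry: one gene per signature, <SIG>_G01 naming as the
# count simulator uses.
toy_registry <- function(genes_per = 1) {
  sigs <- clearseq_signature_names()
  signature_registry(stats::setNames(lapply(sigs, function(s) {
    sprintf("%s_G%02d", toupper(gsub("_", "", s)), seq_len(genes_per))
  }), sigs))
}

# Expression matrix with given values (genes x samples); dimnames invented
# when absent.
toy_expr <- function(values, genes = NULL, samples = NULL) {
  if (is.null(genes)) genes <- sprintf("G%03d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("S%03d", seq_len(ncol(values)))
  dimnames(values) <- list(genes, samples)
  expression_matrix(values, transform = "precomputed")
}

# Score matrix from a samples x 8 numeric matrix (columns in canonical
# signature order unless named).
toy_scores <- function(m, samples = NULL) {
  if (is.null(colnames(m))) colnames(m) <- clearseq_signature_names()
  if (is.null(rownames(m))) {
    rownames(m) <- if (is.null(samples)) sprintf("S%03d", seq_len(nrow(m))) else samples
  }
  signature_scores(m, aggregator = "median")
}

# Scores built directly from the six decision statistics: fixes the
# denominators at 1 so stat columns equal score columns where possible.
#   r3 = ccrcc3_up (ccrcc3_down = 1), r2 = ccrcc2_up / ccrcc1and4_up = s2up
#   (ccrcc1and4_up = 1), r4 = ccrcc4_up (ccrcc1_up = 1)
scores_from_stats <- function(r3, s2up, cc, te, r4) {
  n <- length(r3)
  m <- cbind(ccrcc3_up = r3, ccrcc3_down = rep(1, n), ccrcc2_up = s2up,
             ccrcc1_up = rep(1, n), ccrcc4_up = r4,
             ccrcc1and4_up = rep(1, n), cell_cycle = cc, t_effector = te)
  toy_scores(m)
}
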