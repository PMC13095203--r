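# Brute-force classification oracle, written before and independently of
# classify_cohort(): percentiles by explicit sort + interpolation, the four
# steps applied literally one sample at a time.

oracle_percentile <- function(x, q) {
  s <- sort(x)
  n <- length(s)
  if (n == 1) return(s)
  h <- (q / 100) * (n - 1) + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

oracle_classify <- function(scores_mat) {
  r3 <- scores_mat[, "ccrcc3_up"] / scores_mat[, "ccrcc3_down"]
  s2 <- scores_mat[, "ccrcc2_up"]
  cc <- scores_mat[, "cell_cycle"]
  te <- scores_mat[, "t_effector"]
  r2 <- scores_mat[, "ccrcc2_up"] / scores_mat[, "ccrcc1and4_up"]
  r4 <- scores_mat[, "ccrcc4_up"] / scores_mat[, "ccrcc1_up"]
  n <- nrow(scores_mat)
  lab <- rep(NA_character_, n)
  c1 <- oracle_percentile(r3, 80)
  c2 <- oracle_percentile(s2, 50)
  c3 <- oracle_percentile(cc, 64)
  c4 <- oracle_percentile(te, 75)
  for (i in seq_len(n)) {
    if (r3[i] > c1 && s2[i] <= c2 && cc[i] <= c3 && te[i] <= c4) {
      lab[i] <- "ccrcc3"
    }
  }
  rem <- which(is.na(lab))
  c5 <- oracle_percentile(r2[rem], 50)
  for (i in rem) if (r2[i] > c5) lab[i] <- "ccrcc2"
  rem <- which(is.na(lab))
  c6 <- oracle_percentile(r4[rem], 60)
  for (i in rem) if (r4[i] > c6) lab[i] <- "ccrcc4"
  lab[is.na(lab)] <- "ccrcc1"
  lab
}
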