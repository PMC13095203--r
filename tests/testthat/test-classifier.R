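# Hand-chosen 10-sample cohort exercising every branch of the tree.
# Expected labels were derived with the brute-force oracle (helper-oracle.R)
# before classify_cohort() was written.
toy10 <- function() {
  scores_from_stats(
    r3   = c(3.0, 0.5, 0.8, 1.2, 2.5, 0.6, 0.9, 1.1, 2.8, 0.7),
    s2up = c(2,   8,   7,   3,   9,   4,   6,   5,   1,   2.5),
    cc   = c(1,   5,   4,   6,   2,   3,   7,   8,   1.5, 2.2),
    te   = c(2,   6,   5,   7,   9,   3,   4,   1,   8,   2.5),
    r4   = c(0.5, 1.5, 2.5, 0.7, 0.9, 3.0, 0.4, 1.2, 0.6, 2.0))
}
toy10_labels <- c("ccrcc3", "ccrcc2", "ccrcc2", "ccrcc1", "ccrcc2",
                  "ccrcc4", "ccrcc2", "ccrcc1", "ccrcc1", "ccrcc4")

test_that("percentile follows the linear-interpolation convention", {
  expect_equal(percentile(1:5, 50), 3)
  expect_equal(percentile(1:4, 50), 2.5)
  expect_equal(percentile(c(7, 1, 4), 100), 7)
  expect_equal(percentile(1:4, 0.001), 1, tolerance = 1e-3)
  expect_equal(percentile(1:200, 50), 100.5)
  # matches the hand-rolled oracle on random vectors
  set.seed(8)
  for (i in 1:20) {
    x <- runif(sample(2:30, 1))
    q <- runif(1, 1, 99)
    expect_equal(percentile(x, q), oracle_percentile(x, q))
  }
  expect_error(percentile(numeric(0), 50), class = "clearseq_empty_input")
})

test_that("the 10-sample toy matches the brute-force oracle and frozen labels", {
  sc <- toy10()
  cls <- classify_cohort(sc, min_cohort = 5)
  expect_identical(cls$calls$subtype, toy10_labels)
  expect_identical(cls$calls$subtype, unname(oracle_classify(sc$scores)))
  expect_equal(unname(cls$class_counts), c(3L, 4L, 1L, 2L))
  # rule trace names the step that assigned each label
  expect_match(cls$calls$rule_trace[1], ">ccrcc3$")
  expect_match(cls$calls$rule_trace[2], "s2=T>ccrcc2$")
  expect_match(cls$calls$rule_trace[6], "s3=T>ccrcc4$")
  expect_match(cls$calls$rule_trace[4], "s3=F>ccrcc1$")
})

test_that("classify_cohort equals the oracle on seeded toy cohorts (n <= 12)", {
  set.seed(99)
  for (rep in 1:60) {
    n <- sample(3:12, 1)
    sc <- toy_scores(matrix(runif(n * 8, 1, 10), n))
    cls <- classify_cohort(sc, min_cohort = 3)
    expect_identical(cls$calls$subtype, unname(oracle_classify(sc$scores)))
    # partition: exactly one label per sample, counts sum to n
    expect_equal(sum(cls$class_counts), n)
    expect_true(all(cls$calls$subtype %in% clearseq_subtypes()))
  }
})

test_that("tie-free 200-sample cohort with no ccrcc3 gives the forced 60/100/0/40", {
  sc <- simulate_scores(200, "adversarial_no_ccrcc3", seed = 77)
  cls <- classify_cohort(sc)
  expect_equal(unname(cls$class_counts),
               c(ccrcc1 = 60L, ccrcc2 = 100L, ccrcc3 = 0L, ccrcc4 = 40L),
               ignore_attr = TRUE)
})

test_that("structural class fractions hold on tie-free cohorts", {
  set.seed(13)
  for (rep in 1:10) {
    n <- sample(50:300, 1)
    sc <- toy_scores(matrix(runif(n * 8, 1, 10), n))
    cls <- classify_cohort(sc)
    k3 <- cls$class_counts[["ccrcc3"]]
    expect_lte(k3, ceiling(0.2 * n))
    non3 <- n - k3
    expect_lte(abs(cls$class_counts[["ccrcc2"]] - round(0.5 * non3)), 1)
    rem <- non3 - cls$class_counts[["ccrcc2"]]
    expect_lte(abs(cls$class_counts[["ccrcc4"]] - round(0.4 * rem)), 1)
  }
})

test_that("labels are invariant under sample permutation and duplication", {
  sc <- toy10()
  cls <- classify_cohort(sc, min_cohort = 5)
  set.seed(4)
  perm <- sample(10)
  sc_p <- signature_scores(sc$scores[perm, ], aggregator = "median")
  cls_p <- classify_cohort(sc_p, min_cohort = 5)
  expect_identical(cls_p$calls$subtype, cls$calls$subtype[perm])

  dup <- sc$scores[rep(1:10, each = 2), ]
  rownames(dup) <- sprintf("D%02d", 1:20)
  cls_d <- classify_cohort(signature_scores(dup, aggregator = "median"),
                           min_cohort = 5)
  expect_identical(cls_d$calls$subtype, cls$calls$subtype[rep(1:10, each = 2)])
})

test_that("raising a non-ccrcc3/non-ccrcc2 sample's ccrcc4 ratio only moves it ccrcc1 -> ccrcc4", {
  sc <- toy10()
  seen4 <- FALSE
  for (r4 in c(0.7, 1.0, 1.6, 2.5, 10)) {
    m <- sc$scores
    m[4, "ccrcc4_up"] <- r4           # sample 4 is ccrcc1 at r4 = 0.7
    lab <- classify_cohort(signature_scores(m, aggregator = "median"),
                           min_cohort = 5)$calls$subtype[4]
    expect_true(lab %in% c("ccrcc1", "ccrcc4"))
    if (seen4) expect_identical(lab, "ccrcc4")
    if (lab == "ccrcc4") seen4 <- TRUE
  }
  expect_true(seen4)
})

test_that("fixed-cutoff mode applies the same tree with absolute cutoffs", {
  cuts <- c(p3_ratio = 2, p3_ccrcc2up = 5, p3_cellcycle = 5, p3_teffector = 5,
            p2_ratio = 1.5, p4_ratio = 1.5)
  ts <- threshold_set(mode = "fixed_cutoff", cutoffs = cuts)
  # single sample: everything below its cutoff except the ccrcc4 ratio
  one <- scores_from_stats(r3 = 1, s2up = 1, cc = 1, te = 1, r4 = 3)
  expect_identical(classify_fixed(one, ts)$calls$subtype, "ccrcc4")
  # ccrcc3 ratio above cutoff but T-effector too high: the AND fails
  one2 <- scores_from_stats(r3 = 3, s2up = 1, cc = 1, te = 9, r4 = 1)
  expect_identical(classify_fixed(one2, ts)$calls$subtype, "ccrcc1")
  # all four ccrcc3 criteria met
  one3 <- scores_from_stats(r3 = 3, s2up = 1, cc = 1, te = 1, r4 = 1)
  expect_identical(classify_fixed(one3, ts)$calls$subtype, "ccrcc3")

  expect_error(threshold_set(mode = "fixed_cutoff", cutoffs = cuts[-2]),
               class = "clearseq_incomplete_thresholds")
  expect_error(classify_cohort(toy10(), ts, min_cohort = 5),
               class = "clearseq_invalid_parameter")
})

test_that("extract_cutoffs round-trips: realized values, reuse, serialization", {
  # 200 samples, no ccrcc3 (constant ratio cannot exceed its percentile),
  # ccrcc2 ratio takes the values 1..200
  sc <- scores_from_stats(r3 = rep(1, 200), s2up = 1:200, cc = runif(200),
                          te = runif(200), r4 = runif(200) + 1)
  cls <- classify_cohort(sc)
  expect_equal(cls$class_counts[["ccrcc3"]], 0L)
  ts <- extract_cutoffs(cls)
  expect_equal(unname(ts$cutoffs[["p2_ratio"]]), 100.5)

  # applying the extracted cutoffs back reproduces cohort-mode labels
  expect_identical(classify_fixed(sc, ts)$calls$subtype, cls$calls$subtype)
  sc2 <- toy10()
  cls2 <- classify_cohort(sc2, min_cohort = 5)
  expect_identical(classify_fixed(sc2, extract_cutoffs(cls2))$calls$subtype,
                   cls2$calls$subtype)

  path <- withr::local_tempfile(fileext = ".json")
  write_thresholds(ts, path)
  back <- read_thresholds(path)
  expect_equal(back$cutoffs, ts$cutoffs)
  expect_identical(back$mode, "fixed_cutoff")
  expect_identical(classify_fixed(sc, back)$calls$subtype, cls$calls$subtype)
})

test_that("cohort mode refuses tiny cohorts and incomplete scores", {
  sc <- toy_scores(matrix(runif(5 * 8, 1, 10), 5))
  expect_error(classify_cohort(sc), class = "clearseq_cohort_too_small")
  m7 <- matrix(runif(30 * 7, 1, 10), 30,
               dimnames = list(NULL, clearseq_signature_names()[1:7]))
  rownames(m7) <- sprintf("S%d", 1:30)
  expect_error(classify_cohort(signature_scores(m7, aggregator = "median")),
               class = "clearseq_missing_signature")
})

test_that("concordance reproduces the published cross-tabulation rows", {
  # row with counts (7, 33, 0, 2), total 42 -> percentages (17, 79, 0, 5)
  a <- rep("ccrcc2", 42)
  b <- rep(clearseq_subtypes(), c(7, 33, 0, 2))
  ct <- concordance(a, b)
  expect_equal(unname(ct$counts["ccrcc2", ]), c(7L, 33L, 0L, 2L))
  expect_equal(unname(ct$row_pct["ccrcc2", ]), c(17, 79, 0, 5))
  # row with counts (2, 1, 2, 2), total 7 -> (29, 14, 29, 29)
  ct2 <- concordance(rep("ccrcc3", 7), rep(clearseq_subtypes(), c(2, 1, 2, 2)))
  expect_equal(unname(ct2$row_pct["ccrcc3", ]), c(29, 14, 29, 29))

  # identical labels give a diagonal table with 100% rows
  lab <- rep(clearseq_subtypes(), c(5, 8, 2, 4))
  ct3 <- concordance(lab, lab)
  expect_equal(diag(ct3$counts), c(ccrcc1 = 5L, ccrcc2 = 8L, ccrcc3 = 2L,
                                   ccrcc4 = 4L))
  expect_true(all(diag(ct3$row_pct) == 100))
  expect_equal(sum(ct3$counts), 19)

  # named vectors are aligned by sample; mismatched sets error
  x <- stats::setNames(c("ccrcc1", "ccrcc2"), c("a", "b"))
  y <- stats::setNames(c("ccrcc2", "ccrcc1"), c("b", "a"))
  expect_equal(diag(concordance(x, y)$counts), c(ccrcc1 = 1L, ccrcc2 = 1L,
                                                 ccrcc3 = 0L, ccrcc4 = 0L))
  expect_error(concordance(x, stats::setNames("ccrcc1", "zz")),
               class = "clearseq_sample_mismatch")
})
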