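# A separable score-level fixture: four-centroid scores classified by the
# decision tree provide the labels the SVM must recapture.
separable_fixture <- function(n = 200, seed = 51) {
  sc <- simulate_scores(n, "four_centroid", params = list(separation = 6),
                        seed = seed)
  list(features = sc$scores,
       labels = classify_cohort(sc)$calls$subtype)
}

test_that("rescale_constant_sum hits the target exactly and is idempotent", {
  x <- matrix(c(1, 3, 2, 2), 2, dimnames = list(c("g1", "g2"), c("a", "b")))
  expect_equal(rescale_constant_sum(x[, 1, drop = FALSE], 4),
               x[, 1, drop = FALSE])                      # already at target
  expect_equal(unname(rescale_constant_sum(x, 10)[, "b"]), c(5, 5))
  r1 <- rescale_constant_sum(x, 1e4)
  expect_equal(unname(colSums(r1)), c(1e4, 1e4), tolerance = 1e-9)
  expect_equal(rescale_constant_sum(r1, 1e4), r1)         # fixed point
  x[, 1] <- 0
  expect_error(rescale_constant_sum(x), class = "clearseq_degenerate_sample")
})

test_that("featurize ignores non-signature genes and matches hand arithmetic", {
  reg <- toy_registry(genes_per = 1)
  sig_genes <- unlist(reg, use.names = FALSE)
  v <- matrix(c(1:8, 8:1), ncol = 2,
              dimnames = list(sig_genes, c("s1", "s2")))
  expr <- expression_matrix(v, transform = "precomputed")
  f <- featurize(expr, reg, target_sum = 100)
  expect_equal(dim(f), c(2L, 8L))
  # one gene per signature: feature = gene value * 100 / sample subset sum
  expect_equal(unname(f["s1", ]), (1:8) * 100 / 36, tolerance = 1e-9)
  expect_equal(unname(f["s2", ]), (8:1) * 100 / 36, tolerance = 1e-9)

  # adding unrelated genes changes nothing
  v2 <- rbind(v, matrix(runif(2000, 1, 9), ncol = 2,
                        dimnames = list(sprintf("junk%d", 1:1000), NULL)))
  f2 <- featurize(expression_matrix(v2, transform = "precomputed"), reg,
                  target_sum = 100)
  expect_equal(f2, f, ignore_attr = TRUE)

  # multi-gene hand fixture: 2 genes per signature, median = midpoint
  reg2 <- toy_registry(genes_per = 2)
  g2 <- unlist(reg2, use.names = FALSE)
  raw <- matrix(seq_len(16), ncol = 1, dimnames = list(g2, "s1"))
  f3 <- featurize(expression_matrix(raw, transform = "precomputed"), reg2,
                  target_sum = 1)
  hand <- sapply(seq_len(8), function(i) mean(c(2 * i - 1, 2 * i)) / 136)
  expect_equal(unname(f3["s1", ]), hand, tolerance = 1e-9)
})

test_that("multiclass MCC matches closed forms and the frozen sklearn oracle", {
  lab <- rep(clearseq_subtypes(), 5)
  expect_equal(mcc_multiclass(lab, lab), 1)
  # binary TP=6 TN=3 FP=1 FN=2 -> 16/sqrt(1120)
  tr <- rep(c("pos", "neg"), c(8, 4))
  pr <- c(rep("pos", 6), rep("neg", 2), "pos", rep("neg", 3))
  expect_equal(mcc_multiclass(tr, pr), 16 / sqrt(1120), tolerance = 1e-12)
  # constant predictions are degenerate
  out <- mcc_multiclass(lab, rep("ccrcc1", 20))
  expect_equal(as.numeric(out), 0)
  expect_true(attr(out, "degenerate"))
  # frozen from sklearn.metrics.matthews_corrcoef on this 16-sample fixture
  true16 <- c("ccrcc1", "ccrcc2", "ccrcc3", "ccrcc4", "ccrcc1", "ccrcc2",
              "ccrcc3", "ccrcc4", "ccrcc1", "ccrcc2", "ccrcc2", "ccrcc1",
              "ccrcc4", "ccrcc3", "ccrcc2", "ccrcc1")
  pred16 <- c("ccrcc1", "ccrcc2", "ccrcc3", "ccrcc1", "ccrcc1", "ccrcc2",
              "ccrcc4", "ccrcc4", "ccrcc2", "ccrcc2", "ccrcc2", "ccrcc1",
              "ccrcc4", "ccrcc3", "ccrcc3", "ccrcc1")
  expect_equal(mcc_multiclass(true16, pred16), 0.6595744680851063,
               tolerance = 1e-12)
})

test_that("a separable fixture trains to held-out MCC 1 with confident calls", {
  fx <- separable_fixture()
  bundle <- train_svm(fx$features, fx$labels, seed = 7)
  expect_equal(bundle$heldout_mcc, 1)
  pred <- predict(bundle, fx$features)
  expect_identical(pred$subtype, fx$labels)
  # Platt's prior-corrected targets cap pairwise probabilities below 1, so
  # coupled confidences peak around ~0.95 even on separable data
  expect_gt(median(pred$confidence), 0.9)
  expect_true(all(pred$confidence > 2 / 3))
  # confidences are a distribution over the four classes
  conf <- as.matrix(pred[paste0("conf_", bundle$classes)])
  expect_equal(unname(rowSums(conf)), rep(1, nrow(conf)), tolerance = 1e-6)
  expect_identical(bundle$classes[max.col(conf)], pred$subtype)
})

test_that("shuffled labels give chance-level held-out MCC", {
  sc <- simulate_scores(800, "four_centroid", seed = 52)
  labels <- attr(sc, "true_subtype")
  shuffled <- withr::with_seed(53, sample(unname(labels)))
  bundle <- train_svm(sc$scores, shuffled, seed = 9)
  expect_lte(abs(bundle$heldout_mcc), 0.15)
})

test_that("training is deterministic given seed and validates inputs", {
  fx <- separable_fixture(n = 120, seed = 54)
  b1 <- train_svm(fx$features, fx$labels, seed = 3)
  b2 <- train_svm(fx$features, fx$labels, seed = 3)
  expect_identical(b1[names(b1) != "pairs"], b2[names(b2) != "pairs"])
  expect_equal(b1$pairs, b2$pairs, tolerance = 0)
  b3 <- train_svm(fx$features, fx$labels, seed = 4)
  expect_false(identical(b1$heldout_samples, b3$heldout_samples))

  expect_error(train_svm(fx$features, rep("ccrcc1", 120), seed = 1),
               class = "clearseq_invalid_parameter")
  labs <- fx$labels
  labs[labs == "ccrcc3"] <- "ccrcc1"
  labs[1] <- "ccrcc3"                       # a singleton class
  expect_error(train_svm(fx$features, labs, seed = 1),
               class = "clearseq_degenerate_split")
  expect_error(train_svm(fx$features, fx$labels),
               class = "clearseq_invalid_parameter")  # seed mandatory
})

test_that("prediction is per-sample: no cross-sample leakage, scale invariant", {
  reg <- toy_registry(genes_per = 2)
  set.seed(55)
  genes <- c(unlist(reg, use.names = FALSE), sprintf("bg%d", 1:20))
  vals <- matrix(runif(length(genes) * 120, 1, 10), length(genes),
                 dimnames = list(genes, sprintf("S%d", 1:120)))
  expr <- expression_matrix(vals, transform = "precomputed")
  feats <- featurize(expr, reg)
  labels <- classify_cohort(score_all(expr, reg))$calls$subtype
  bundle <- train_svm(feats, labels, seed = 21)

  full <- predict(bundle, expr)
  # single sample alone gets the identical prediction
  one <- expression_matrix(vals[, 5, drop = FALSE], transform = "precomputed")
  single <- predict(bundle, one)
  expect_identical(single$subtype, full$subtype[5])
  expect_equal(as.numeric(single[1, -(1:2)]), as.numeric(full[5, -(1:2)]),
               tolerance = 1e-12)

  # multiplying one sample's raw values by a positive constant changes nothing
  vals2 <- vals
  vals2[, 5] <- vals2[, 5] * 37.5
  pred2 <- predict(bundle, expression_matrix(vals2, transform = "precomputed"))
  expect_identical(pred2$subtype, full$subtype)
  expect_equal(pred2$confidence, full$confidence, tolerance = 1e-9)
})

test_that("bundle JSON round-trip reproduces predictions bit-identically", {
  fx <- separable_fixture(n = 120, seed = 56)
  bundle <- train_svm(fx$features, fx$labels, seed = 5)
  path <- withr::local_tempfile(fileext = ".json")
  write_svm_bundle(bundle, path)
  back <- read_svm_bundle(path)
  p1 <- predict(bundle, fx$features)
  p2 <- predict(back, fx$features)
  expect_identical(p1, p2)
  expect_equal(back$heldout_mcc, bundle$heldout_mcc)
})

test_that("SVM recaptures decision-tree labels on well-separated cohorts", {
  fx <- separable_fixture(n = 400, seed = 57)
  bundle <- train_svm(fx$features, fx$labels, seed = 11)
  expect_gte(bundle$heldout_mcc, 0.95)
})
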