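# Single-sample classification: subset to the signature genes, rescale each
# sample to a constant sum (so predictions are invariant to library size and
# to inter-dataset scale differences), compute median signature scores, and
# classify the 8-dimensional score vector with a linear multiclass SVM.
# The SVM is a C-SVC solved in the dual with quadprog (one-vs-one, balanced
# class weights), confidence values come from per-pair Platt-calibrated
# probabilities combined by pairwise coupling.

#' Rescale each sample to a constant sum
#'
#' @param x Numeric matrix, genes x samples, each sample's sum > 0.
#' @param target_sum The sum every column is scaled to (default 1e4; an
#'   arbitrary positive constant, downstream results do not depend on it).
#' @return Matrix with each column summing to `target_sum`. Idempotent.
#' @export
rescale_constant_sum <- function(x, target_sum = 1e4) {
  cs_assert(is.matrix(x) && is.numeric(x), "malformed_matrix",
            "x must be a numeric matrix")
  cs_assert(target_sum > 0, "invalid_parameter", "target_sum must be positive")
  sums <- colSums(x)
  bad <- which(sums <= 0)
  cs_assert(length(bad) == 0, "degenerate_sample",
            "sample(s) with nonpositive sum over the gene subset: %s",
            paste(colnames(x)[bad], collapse = ", "))
  sweep(x, 2, sums / target_sum, "/")
}

#' Compute the SVM feature matrix (signature scores on the rescaled subset)
#'
#' Subsets the expression matrix to the union of the eight signatures'
#' genes, rescales each sample to `target_sum`, and computes median
#' signature scores. Features are per-sample quantities: they do not depend
#' on which other samples are present, nor on genes outside the signature
#' union.
#'
#' @param expr An [expression_matrix()].
#' @param registry A classification-ready [signature_registry()].
#' @param target_sum Constant sum per sample (see [rescale_constant_sum()]).
#' @param min_fraction Per-signature coverage rule, as in [score_signature()].
#' @return Numeric matrix, samples x eight signatures, with attributes
#'   `genes` (the subset used), `target_sum` and `registry`.
#' @export
featurize <- function(expr, registry, target_sum = 1e4, min_fraction = 0.5) {
  stopifnot(inherits(expr, "expression_matrix"),
            inherits(registry, "signature_registry"))
  cs_assert(classification_ready(registry), "missing_signature",
            "registry is missing classification signatures")
  union_genes <- unique(unlist(registry[clearseq_signature_names()],
                               use.names = FALSE))
  idx <- match(gene_key(union_genes), gene_key(rownames(expr$values)))
  present <- rownames(expr$values)[stats::na.omit(idx)]
  cs_assert(length(present) > 0, "insufficient_coverage",
            "none of the signature genes are present")
  sub <- rescale_constant_sum(expr$values[present, , drop = FALSE], target_sum)
  sub_expr <- expression_matrix(sub, transform = "precomputed")
  scores <- score_all(sub_expr, registry, aggregator = "median",
                      min_fraction = min_fraction)
  structure(scores$scores, genes = present, target_sum = target_sum,
            registry = unclass_registry(registry))
}

unclass_registry <- function(registry) {
  lapply(registry[clearseq_signature_names()], as.character)
}

# ---- binary C-SVC (linear kernel) via the dual QP ----------------------

svm_fit_binary <- function(X, y, C_pos, C_neg) {
  n <- nrow(X)
  K <- tcrossprod(X)
  D <- (y %o% y) * K
  diag(D) <- diag(D) + 1e-8 * max(1, mean(diag(K)))
  Cvec <- ifelse(y > 0, C_pos, C_neg)
  Amat <- cbind(y, diag(n), -diag(n))
  bvec <- c(0, rep(0, n), -Cvec)
  sol <- quadprog::solve.QP(D, rep(1, n), Amat, bvec, meq = 1)
  alpha <- pmin(pmax(sol$solution, 0), Cvec)
  w <- drop(crossprod(X, alpha * y))
  f_no_b <- drop(X %*% w)
  tol <- 1e-6 * max(Cvec)
  free <- alpha > tol & alpha < Cvec - tol
  b <- if (any(free)) {
    mean(y[free] - f_no_b[free])
  } else {
    sv <- alpha > tol
    mean(y[sv] - f_no_b[sv])
  }
  list(w = w, b = b)
}

# ---- Platt calibration: P(y = +1 | f) = 1 / (1 + exp(A f + B)) ---------
# Newton iteration on the regularized log-likelihood with prior-corrected
# targets (the standard numerically stable formulation).

platt_fit <- function(f, y) {
  n_pos <- sum(y > 0)
  n_neg <- sum(y <= 0)
  hi <- (n_pos + 1) / (n_pos + 2)
  lo <- 1 / (n_neg + 2)
  t <- ifelse(y > 0, hi, lo)
  A <- 0
  B <- log((n_neg + 1) / (n_pos + 1))
  nll <- function(A, B) {
    z <- A * f + B
    sum(ifelse(z >= 0, t * z + log1p(exp(-z)), (t - 1) * z + log1p(exp(z))))
  }
  val <- nll(A, B)
  for (it in 1:100) {
    z <- A * f + B
    p <- 1 / (1 + exp(z))      # P(y=+1)
    q <- 1 - p
    g <- t - p                 # d nll / dz
    gA <- sum(g * f)
    gB <- sum(g)
    h <- p * q                 # d2 nll / dz2
    hAA <- sum(h * f * f) + 1e-12
    hBB <- sum(h) + 1e-12
    hAB <- sum(h * f)
    if (max(abs(gA), abs(gB)) < 1e-10) break
    det <- hAA * hBB - hAB^2
    dA <- -(hBB * gA - hAB * gB) / det
    dB <- -(-hAB * gA + hAA * gB) / det
    step <- 1
    repeat {
      A2 <- A + step * dA
      B2 <- B + step * dB
      v2 <- nll(A2, B2)
      if (v2 < val + 1e-4 * step * (gA * dA + gB * dB) || step < 1e-10) break
      step <- step / 2
    }
    A <- A + step * dA
    B <- B + step * dB
    val <- nll(A, B)
  }
  list(A = A, B = B)
}

platt_prob <- function(f, cal) 1 / (1 + exp(cal$A * f + cal$B))

# ---- pairwise coupling of one-vs-one probabilities ---------------------
# Given r[i, j] = P(class i | i or j), solve for p minimizing
# sum_{i<j} (r_ji p_i - r_ij p_j)^2 subject to sum p = 1 (the standard
# second coupling method), by the convergent fixed-point iteration.

couple_pairwise <- function(r) {
  k <- nrow(r)
  Q <- matrix(0, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) {
        Q[i, i] <- sum(r[-i, i]^2)
      } else {
        Q[i, j] <- -r[j, i] * r[i, j]
      }
    }
  }
  p <- rep(1 / k, k)
  for (it in 1:200) {
    qp <- drop(Q %*% p)
    obj <- drop(crossprod(p, qp))
    if (max(abs(qp - obj)) < 1e-12) break
    for (i in seq_len(k)) {
      p[i] <- (-sum(Q[i, -i] * p[-i]) + drop(crossprod(p, Q %*% p))) / Q[i, i]
      p <- p / sum(p)
    }
  }
  p
}

#' Multiclass Matthews correlation coefficient
#'
#' The covariance-form generalization computed from the full K x K
#' confusion matrix; it reduces to the usual binary MCC for K = 2. When the
#' denominator is degenerate (all predictions or all truths in one class)
#' the value is 0, flagged with attribute `degenerate`.
#'
#' @param labels_true,labels_pred Equal-length label vectors.
#' @return MCC in `[-1, 1]`.
#' @export
mcc_multiclass <- function(labels_true, labels_pred) {
  cs_assert(length(labels_true) == length(labels_pred) && length(labels_true) >= 1,
            "invalid_parameter", "label vectors must be non-empty and equal length")
  n <- length(labels_true)
  correct <- sum(labels_true == labels_pred)
  tk <- table(labels_true)
  pk <- table(factor(labels_pred, levels = union(labels_pred, labels_true)))
  cross <- sum(vapply(names(tk), function(k) {
    as.numeric(tk[[k]]) * as.numeric(sum(labels_pred == k))
  }, numeric(1)))
  num <- correct * n - cross
  den <- sqrt(n^2 - sum(as.numeric(pk)^2)) * sqrt(n^2 - sum(as.numeric(tk)^2))
  if (den == 0) return(structure(0, degenerate = TRUE))
  num / den
}

#' Train the single-sample SVM on signature-score features
#'
#' Splits the cohort stratified by class (fraction `split_fraction` to
#' training), standardizes features on the training set, fits a linear
#' one-vs-one C-SVC with balanced class weights, Platt-calibrates each
#' pairwise decision function, and reports the multiclass MCC on the
#' held-out samples.
#'
#' @param features Samples x signatures matrix from [featurize()] (or any
#'   numeric feature matrix with row/column names).
#' @param labels Per-sample subtype labels (>= 2 classes, each with >= 2
#'   samples).
#' @param split_fraction Fraction used for training (default 0.8).
#' @param seed Integer seed for the stratified split (mandatory).
#' @param cost Soft-margin cost parameter C (default 1).
#' @return An object of class `clearseq_svm`: the trained pairwise models,
#'   standardization parameters, featurization settings (gene list, target
#'   sum, registry) when `features` came from [featurize()], and training
#'   metadata including `heldout_mcc` and the held-out sample IDs.
#' @export
train_svm <- function(features, labels, split_fraction = 0.8, seed,
                      cost = 1) {
  cs_assert(is.matrix(features) && is.numeric(features), "malformed_matrix",
            "features must be a numeric matrix")
  cs_assert(!missing(seed) && is.finite(seed), "invalid_parameter",
            "a split seed is mandatory")
  cs_assert(length(labels) == nrow(features), "invalid_parameter",
            "one label per feature row required")
  cs_assert(split_fraction > 0 && split_fraction < 1, "invalid_parameter",
            "split_fraction must lie in (0, 1)")
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  cs_assert(length(classes) >= 2, "invalid_parameter",
            ">= 2 classes required (got %d)", length(classes))
  tiny <- classes[table(factor(labels, classes)) < 2]
  cs_assert(length(tiny) == 0, "degenerate_split",
            "class(es) with fewer than 2 samples: %s",
            paste(tiny, collapse = ", "))

  n <- nrow(features)
  train_idx <- with_local_seed(seed, {
    unlist(lapply(classes, function(cl) {
      idx <- which(labels == cl)
      n_tr <- max(1, min(length(idx) - 1, round(split_fraction * length(idx))))
      sample(idx, n_tr)
    }), use.names = FALSE)
  })
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(n), train_idx)
  cs_assert(all(classes %in% labels[train_idx]), "degenerate_split",
            "a class is absent from the training split")

  Xtr <- features[train_idx, , drop = FALSE]
  center <- colMeans(Xtr)
  scale_ <- apply(Xtr, 2, stats::sd)
  scale_[scale_ == 0] <- 1
  Ztr <- scale(Xtr, center = center, scale = scale_)
  ytr <- labels[train_idx]

  pairs <- list()
  for (i in seq_along(classes)) {
    for (j in seq_along(classes)) {
      if (j <= i) next
      sel <- ytr %in% c(classes[i], classes[j])
      Xp <- Ztr[sel, , drop = FALSE]
      yp <- ifelse(ytr[sel] == classes[i], 1, -1)
      np <- sum(yp > 0)
      nn <- sum(yp < 0)
      # balanced class weights: C_k = cost * n_pair / (2 n_k)
      fit <- svm_fit_binary(Xp, yp,
                            C_pos = cost * length(yp) / (2 * np),
                            C_neg = cost * length(yp) / (2 * nn))
      f <- drop(Xp %*% fit$w) + fit$b
      cal <- platt_fit(f, yp)
      pairs[[length(pairs) + 1]] <- list(pos = classes[i], neg = classes[j],
                                         w = fit$w, b = fit$b,
                                         A = cal$A, B = cal$B)
    }
  }

  bundle <- structure(list(classes = classes,
                           feature_names = colnames(features),
                           center = center, scale = scale_,
                           pairs = pairs, cost = cost,
                           genes = attr(features, "genes"),
                           target_sum = attr(features, "target_sum"),
                           registry = attr(features, "registry"),
                           split_fraction = split_fraction, seed = seed,
                           heldout_mcc = NA_real_,
                           heldout_samples = rownames(features)[test_idx]),
                      class = "clearseq_svm")
  if (length(test_idx) > 0) {
    pred <- predict(bundle, features[test_idx, , drop = FALSE])
    bundle$heldout_mcc <- as.numeric(mcc_multiclass(labels[test_idx],
                                                    pred$subtype))
  }
  bundle
}

#' @export
print.clearseq_svm <- function(x, ...) {
  cat(sprintf("clearseq_svm: linear one-vs-one C-SVC, classes %s\n",
              paste(x$classes, collapse = "/")))
  cat(sprintf("  cost=%g, split=%.2f, seed=%s, held-out MCC=%s\n", x$cost,
              x$split_fraction, format(x$seed),
              ifelse(is.na(x$heldout_mcc), "NA", sprintf("%.4f", x$heldout_mcc))))
  invisible(x)
}

#' Predict subtypes with confidence values
#'
#' Accepts either an [expression_matrix()] (featurized with the bundle's
#' gene list, target sum and registry) or an already-computed feature
#' matrix. Each sample is processed independently — a single sample gets
#' the same prediction alone as within a larger matrix. Confidence values
#' are pairwise-coupled Platt probabilities over the classes, summing to 1;
#' the label is the argmax class.
#'
#' @param object A `clearseq_svm` bundle.
#' @param newdata [expression_matrix()] or samples x signatures matrix.
#' @param ... Unused.
#' @return Data frame with `sample_id`, `subtype`, `confidence` (the top
#'   class probability) and one `conf_<class>` column per class.
#' @export
predict.clearseq_svm <- function(object, newdata, ...) {
  if (inherits(newdata, "expression_matrix")) {
    cs_assert(!is.null(object$registry), "invalid_parameter",
              "bundle has no featurization info; pass a feature matrix")
    reg <- signature_registry(object$registry)
    newdata <- featurize(newdata, reg, target_sum = object$target_sum)
  }
  cs_assert(is.matrix(newdata) && is.numeric(newdata), "malformed_matrix",
            "newdata must be an expression_matrix or numeric feature matrix")
  if (!is.null(colnames(newdata)) && !is.null(object$feature_names)) {
    cs_assert(all(object$feature_names %in% colnames(newdata)),
              "missing_signature", "feature columns do not match the bundle")
    newdata <- newdata[, object$feature_names, drop = FALSE]
  }
  Z <- scale(newdata, center = object$center, scale = object$scale)
  k <- length(object$classes)
  n <- nrow(Z)
  probs <- matrix(NA_real_, n, k, dimnames = list(rownames(newdata),
                                                  object$classes))
  r_arrays <- lapply(object$pairs, function(p) {
    f <- drop(Z %*% p$w) + p$b
    platt_prob(f, p)      # P(pos class | pos or neg)
  })
  for (s in seq_len(n)) {
    r <- matrix(0, k, k)
    for (pi in seq_along(object$pairs)) {
      p <- object$pairs[[pi]]
      i <- match(p$pos, object$classes)
      j <- match(p$neg, object$classes)
      rij <- min(max(r_arrays[[pi]][s], 1e-7), 1 - 1e-7)
      r[i, j] <- rij
      r[j, i] <- 1 - rij
    }
    probs[s, ] <- couple_pairwise(r)
  }
  lab <- object$classes[apply(probs, 1, which.max)]
  out <- data.frame(sample_id = if (is.null(rownames(newdata)))
    as.character(seq_len(n)) else rownames(newdata),
    subtype = lab,
    confidence = apply(probs, 1, max),
    stringsAsFactors = FALSE)
  for (ci in seq_len(k)) out[[paste0("conf_", object$classes[ci])]] <- probs[, ci]
  rownames(out) <- NULL
  out
}

#' Serialize an SVM bundle to JSON
#'
#' Full-precision JSON so that save, load and predict is bit-identical to
#' predicting in memory.
#'
#' @param bundle A `clearseq_svm`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_svm_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "clearseq_svm"))
  obj <- unclass(bundle)
  obj$center <- as.list(obj$center)
  obj$scale <- as.list(stats::setNames(obj$scale, names(obj$center)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

#' Load an SVM bundle from JSON
#' @param path Path written by [write_svm_bundle()].
#' @return A `clearseq_svm`.
#' @export
read_svm_bundle <- function(path) {
  cs_assert(file.exists(path), "io_failure", "file not found: %s", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  feature_names <- obj$feature_names
  pairs <- lapply(seq_len(nrow(obj$pairs)), function(i) {
    list(pos = obj$pairs$pos[i], neg = obj$pairs$neg[i],
         w = stats::setNames(as.numeric(obj$pairs$w[[i]]), feature_names),
         b = obj$pairs$b[i], A = obj$pairs$A[i], B = obj$pairs$B[i])
  })
  structure(list(classes = obj$classes,
                 feature_names = feature_names,
                 center = unlist(obj$center),
                 scale = stats::setNames(unlist(obj$scale), names(obj$center)),
                 pairs = pairs, cost = obj$cost,
                 genes = obj$genes,
                 target_sum = obj$target_sum,
                 registry = lapply(obj$registry, as.character),
                 split_fraction = obj$split_fraction, seed = obj$seed,
                 heldout_mcc = obj$heldout_mcc,
                 heldout_samples = obj$heldout_samples),
            class = "clearseq_svm")
}
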