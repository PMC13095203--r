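# Parametric empirical-Bayes batch correction (location/scale model, no
# biological covariates). Per gene g, sample j in batch i:
#   Y_ijg = alpha_g + gamma_ig + delta_ig * eps_ijg
# Gene-wise standardized data are shrunk toward batch-level priors:
# normal prior on the location gamma, inverse-gamma prior on the squared
# scale delta^2, hyperparameters estimated from the gene ensemble by
# moments, posterior solved by the standard fixed-point iteration.

#' Fit the empirical-Bayes batch model
#'
#' @param expr An [expression_matrix()].
#' @param batch Per-sample batch labels; taken from `expr$batch` when
#'   omitted. At least 2 batches with >= 2 samples each.
#' @return An object of class `batch_model` holding, per (batch, gene), the
#'   shrunk location (`gamma_star`) and squared-scale (`delta2_star`)
#'   estimates, the gene-wise grand means and pooled variances used for
#'   standardization, and the per-batch prior hyperparameters.
#' @export
combat_fit <- function(expr, batch = NULL) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (is.null(batch)) batch <- expr$batch
  cs_assert(!is.null(batch), "invalid_parameter", "no batch labels supplied")
  batch <- as.character(batch)
  cs_assert(length(batch) == ncol(expr$values), "invalid_parameter",
            "batch labels must be one per sample")
  levels <- unique(batch)
  nb <- table(factor(batch, levels = levels))
  cs_assert(length(levels) >= 2, "insufficient_batch",
            "batch correction needs >= 2 batches (got %d)", length(levels))
  small <- names(nb)[nb < 2]
  cs_assert(length(small) == 0, "insufficient_batch",
            "batch(es) with fewer than 2 samples: %s",
            paste(small, collapse = ", "))

  dat <- expr$values
  n <- ncol(dat)
  batch_means <- vapply(levels, function(b) {
    rowMeans(dat[, batch == b, drop = FALSE])
  }, numeric(nrow(dat)))                                   # genes x batches
  w <- as.numeric(nb) / n
  grand_mean <- drop(batch_means %*% w)
  var_pooled <- rowMeans((dat - batch_means[, match(batch, levels)])^2)
  cs_assert(all(var_pooled > 0), "invalid_parameter",
            "gene(s) constant within every batch: %s",
            paste(utils::head(rownames(dat)[var_pooled == 0], 5), collapse = ", "))
  z <- (dat - grand_mean) / sqrt(var_pooled)

  gamma_hat <- vapply(levels, function(b) {
    rowMeans(z[, batch == b, drop = FALSE])
  }, numeric(nrow(dat)))
  delta2_hat <- vapply(levels, function(b) {
    apply(z[, batch == b, drop = FALSE], 1, stats::var)
  }, numeric(nrow(dat)))

  gamma_star <- gamma_hat
  delta2_star <- delta2_hat
  priors <- vector("list", length(levels))
  names(priors) <- levels
  for (bi in seq_along(levels)) {
    b <- levels[bi]
    ni <- as.numeric(nb[bi])
    g_bar <- mean(gamma_hat[, bi])
    t2 <- stats::var(gamma_hat[, bi])
    m <- mean(delta2_hat[, bi])
    s2 <- stats::var(delta2_hat[, bi])
    a_prior <- (2 * s2 + m^2) / s2
    b_prior <- (m * s2 + m^3) / s2
    priors[[bi]] <- list(gamma_bar = g_bar, tau2_bar = t2,
                         a_prior = a_prior, b_prior = b_prior)
    zb <- z[, batch == b, drop = FALSE]
    g_old <- gamma_hat[, bi]
    d_old <- delta2_hat[, bi]
    repeat {
      g_new <- (ni * t2 * gamma_hat[, bi] + d_old * g_bar) / (ni * t2 + d_old)
      ss <- rowSums((zb - g_new)^2)
      d_new <- (0.5 * ss + b_prior) / (ni / 2 + a_prior - 1)
      change <- max(abs(g_new - g_old) / abs(g_old),
                    abs(d_new - d_old) / d_old)
      g_old <- g_new
      d_old <- d_new
      if (change < 1e-4) break
    }
    gamma_star[, bi] <- g_old
    delta2_star[, bi] <- d_old
  }

  structure(list(batches = levels,
                 n_per_batch = stats::setNames(as.numeric(nb), levels),
                 gene_ids = rownames(dat),
                 grand_mean = grand_mean,
                 var_pooled = var_pooled,
                 gamma_hat = gamma_hat,
                 delta2_hat = delta2_hat,
                 gamma_star = gamma_star,
                 delta2_star = delta2_star,
                 priors = priors),
            class = "batch_model")
}

#' @export
print.batch_model <- function(x, ...) {
  cat(sprintf("batch_model: %d genes x %d batches (%s)\n",
              length(x$gene_ids), length(x$batches),
              paste(x$batches, collapse = ", ")))
  invisible(x)
}

#' Apply a fitted batch model
#'
#' Standardizes each gene with the model's grand mean and pooled variance,
#' removes the shrunk batch location, divides by the shrunk batch scale and
#' restores the original scale, homogenizing per-gene batch means and
#' variances.
#'
#' @param expr An [expression_matrix()] with the model's genes.
#' @param model A `batch_model` from [combat_fit()].
#' @param batch Per-sample batch labels; taken from `expr$batch` when
#'   omitted. Must all be known to the model.
#' @return The corrected [expression_matrix()] (`batch_corrected = TRUE`).
#' @export
combat_apply <- function(expr, model, batch = NULL) {
  stopifnot(inherits(expr, "expression_matrix"), inherits(model, "batch_model"))
  if (is.null(batch)) batch <- expr$batch
  cs_assert(!is.null(batch), "invalid_parameter", "no batch labels supplied")
  batch <- as.character(batch)
  cs_assert(identical(rownames(expr$values), model$gene_ids), "invalid_parameter",
            "expression genes do not match the fitted model")
  unseen <- setdiff(unique(batch), model$batches)
  cs_assert(length(unseen) == 0, "unknown_batch",
            "batch label(s) not in the fitted model: %s",
            paste(unseen, collapse = ", "))
  bi <- match(batch, model$batches)
  z <- (expr$values - model$grand_mean) / sqrt(model$var_pooled)
  adj <- (z - model$gamma_star[, bi, drop = FALSE]) /
    sqrt(model$delta2_star)[, bi, drop = FALSE]
  out <- adj * sqrt(model$var_pooled) + model$grand_mean
  res <- expression_matrix(out, size_factors = expr$size_factors,
                           transform = expr$transform, batch = batch,
                           batch_corrected = TRUE)
  res
}

#' Fit-and-apply batch correction
#'
#' Single-batch input is returned unchanged (nothing to correct).
#'
#' @inheritParams combat_fit
#' @return Corrected [expression_matrix()].
#' @export
combat <- function(expr, batch = NULL) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (is.null(batch)) batch <- expr$batch
  cs_assert(!is.null(batch), "invalid_parameter", "no batch labels supplied")
  if (length(unique(as.character(batch))) < 2) return(expr)
  combat_apply(expr, combat_fit(expr, batch), batch)
}
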