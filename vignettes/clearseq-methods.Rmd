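---
title: "Methods: ccRCC subtype classification with clearseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ccRCC subtype classification with clearseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clearseq)
```

This vignette is the package's own account of its models and of the design
choices made where the design was genuinely open. It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## The classification model

Clear-cell renal cell carcinoma separates into four reproducible bulk
transcriptomic subtypes. The classifier works entirely on **eight gene
signature scores** per sample, each the median expression of a gene set on
a variance-stabilized scale, and assigns labels with a four-step decision
tree driven by cohort percentiles:

1. **ccrcc3** ("normal kidney-like"): the ratio of the `ccrcc3_up` score
   to the `ccrcc3_down` score lies strictly above the cohort's 80th
   percentile, *and* `ccrcc2_up` is at or below its 50th percentile, *and*
   `cell_cycle` at or below its 64th, *and* `t_effector` at or below its
   75th. All four percentiles are taken over the full cohort.
2. **ccrcc2** (angiogenesis-enriched): among samples not called ccrcc3,
   the ratio `ccrcc2_up / ccrcc1and4_up` lies strictly above the 50th
   percentile of that ratio *computed over those remaining samples*.
3. **ccrcc4** (inflamed/aggressive): among still-unlabeled samples, the
   ratio `ccrcc4_up / ccrcc1_up` lies strictly above its 60th percentile
   over *those* samples (the "highest 40th percentile").
4. **ccrcc1**: everything else.

Assumptions worth spelling out: scores must be positive (ratios are taken
on the `log2(normalized + 1)` scale, where that holds for any reasonably
expressed signature), the cohort must be large enough for percentiles to
be stable, and the cohort's subtype composition must resemble the
reference population — the percentile rules were calibrated to reproduce a
reference distribution, so a cohort consisting of, say, only angiogenic
tumors will still be split 50/50 at step 2. For such cohorts, and for
single samples, the package supports **fixed-cutoff mode**: the six
realized cutoffs of a reference cohort (`extract_cutoffs()`) replace the
percentiles. Fixed cutoffs are only meaningful when preprocessing matches
the reference cohort's closely.

### Numerical conventions

* **Quantile convention.** All percentiles use linear interpolation with
  the k-th of n sorted values at percent 100(k−1)/(n−1) (R's default,
  type 7). The convention is pinned in one exported primitive
  (`percentile()`) and verified against a hand-rolled sort-and-interpolate
  oracle.
* **Inequality directions.** "Upper/highest" criteria are strict `>`;
  "lower/lowest" criteria are inclusive `<=`. Samples exactly at a cutoff
  therefore fall on the inclusive side of "low" rules and outside "high"
  rules; each sample's `rule_trace` records the four step-1 comparisons
  and the step that assigned its label.
* **Reference populations.** Step 1 percentiles are over all samples;
  steps 2 and 3 are over the not-yet-labeled samples only. This is the
  only reading that yields the intended class proportions (half of
  non-ccrcc3 becomes ccrcc2, 40% of the remainder ccrcc4), which the
  structural acceptance test checks exactly on tie-free cohorts.
* **Cohort floor.** Cohort mode refuses n < 20 (`min_cohort`,
  configurable): percentiles of tiny cohorts are unstable, and fixed-cutoff
  mode is the intended path there.
* Ties between samples are resolved purely by value comparison; with
  continuous scores they occur with probability zero. Duplicating every
  sample of a tie-free cohort leaves labels unchanged whenever the doubled
  quantile positions stay inside the same inter-value interval; this holds
  at the 50/60/80 percentiles used on tie-free data and is tested, but is
  not a theorem for arbitrary percentile settings under type-7
  interpolation.

## Preprocessing

* **Gene filter**: keep genes with CPM strictly above `cpm_threshold`
  (default 1) in at least `min_samples` samples (default 50). CPM uses
  library sizes over *all* genes, before filtering.
* **Sample filter**: keep samples whose count sum over retained genes is
  strictly greater than `min_total` (default 500,000 counts). Both
  defaults assume a transcriptome-scale panel and a several-hundred-sample
  cohort; they are configuration keys precisely so that small simulated
  panels (a few hundred genes, ~1e5 counts/sample) can scale them down.
  Filters act on the merged cohort, not per batch (configurable upstream
  by splitting input).
* **Size factors**: median-of-ratios — per-gene geometric-mean reference
  over all-positive genes, per-sample median of count/reference. A single
  sample gets size factor 1 by construction. The implementation is tested
  against DESeq2's `estimateSizeFactorsForMatrix` as an independent
  oracle.
* **Variance-stabilizing transform**: `log2(count/size_factor + 1)`. A
  dispersion-trend closed form would differ mainly at low counts; the
  decision rules depend only on medians and ratios of signature scores,
  which are rank-stable under any monotone log-like transform. The
  transform name is recorded on the object so an externally computed VST
  can be supplied (`transform = "precomputed"`).

### Batch correction

Parametric empirical-Bayes location/scale adjustment without biological
covariates. Per gene, data are standardized with the weighted grand mean
and the pooled within-batch variance; per-batch locations γ and squared
scales δ² are estimated per gene, then shrunk toward batch-level priors
(normal for γ, inverse-gamma for δ², hyperparameters by the method of
moments across genes) via the standard fixed-point iteration (convergence
1e-4); corrected data are unstandardized.

Two honest caveats, both verified numerically in `test-combat.R`:

* **Shrinkage leaves per-gene residuals.** EB deliberately retains the
  fraction (1−k) of each gene's deviation from the batch-level prior mean,
  k = n·τ²/(n·τ² + δ²). With 100 samples per batch a planted constant
  shift of 2 is removed to ~96% on average, but individual genes can
  retain batch-mean gaps of a few tenths of a pooled SD. Consequently the
  correction is **not exactly idempotent** (a second pass changes values
  by < 10% of the first) and the per-gene grand mean is preserved only
  approximately (drift < 0.02 pooled SD in the tested balanced designs).
* Batches need at least 2 samples, and genes that are constant within
  every batch are rejected rather than silently dropped.

## Signature scoring

Gene symbols are matched case-insensitively after trimming, because
signature files typically carry upper-case symbols while matrices may not.
At least `min_fraction` (default 0.5) of a signature's genes must be
present; the score is then computed over the present genes only, and the
genes used are recorded. The even-count median is the midpoint of the two
central order statistics — the standard convention; it also makes mean and
median coincide for 1- and 2-gene signatures. Single-cell mode changes
only the aggregator to the mean.

## The single-sample SVM

The decision tree needs a cohort; the SVM does not. Features are computed
strictly per sample: subset the matrix to the union of the eight
signatures' genes, rescale each sample's subset to a constant sum
(`target_sum = 1e4`; predictions are provably invariant to the constant
and to any per-sample scaling of the input, which is what makes the model
portable across datasets), then take median signature scores — an
8-dimensional feature vector.

The classifier itself is a **linear soft-margin C-SVC**, trained one-vs-one
with balanced class weights (C_k = C·n/(2·n_k)) on features standardized
by the training split. Kernel and regularization were not prescribed
anywhere, so the package pins the simplest defensible choice: a linear
kernel in an 8-dimensional, already biologically meaningful feature space,
cost 1, both exposed as arguments. The dual QP is solved exactly with
`quadprog` (a ridge of 1e-8 on the Gram diagonal for positive
definiteness); the bias is recovered from the free support vectors.

**Confidence values** are pairwise Platt calibration followed by pairwise
coupling: each binary decision value is mapped through a sigmoid fitted by
Newton iteration on prior-corrected targets (t₊ = (N₊+1)/(N₊+2)), and the
6 pairwise probabilities are combined into a 4-class distribution by the
standard quadratic coupling method solved by its convergent fixed-point
iteration. Two consequences: confidences always sum to 1 and the label is
the argmax (ties broken toward the first class in sorted order), and the
prior correction bounds pairwise probabilities away from 0 and 1 — even on
perfectly separated data the top confidence peaks around 0.95-0.99 rather
than 1.0. That is a feature of calibration, not a defect.

Training uses a stratified split (default 80/20, seed mandatory; every
class is guaranteed at least one sample on each side or training aborts
with a classed error) and reports the **multiclass Matthews correlation
coefficient** on the held-out samples, computed in covariance form from
the full confusion matrix; it reduces to the binary MCC at K = 2 and is 0
(flagged) when either label vector is constant. Bundles serialize to JSON
at 17 significant digits, which round-trips IEEE doubles exactly, so
save → load → predict is bit-identical.

## The synthetic cohort generator

`simulate_counts()` states a world, not a dial:

* **Counts** are negative binomial with Var = μ + φμ², φ = 0.1 — a typical
  bulk RNA-seq dispersion. Per-gene base means are log-uniform on
  [100, 1000].
* **Subtype structure**: each subtype shifts its defining signatures'
  genes on the log2 scale by `effect_size` (default 4) within-class SDs,
  where the within-class SD of log2 expression of an NB gene is
  √(1/μ + φ)/ln 2. The archetypes mirror the biology the labels describe:
  ccrcc2 raises `ccrcc2_up`; ccrcc1 raises `ccrcc1_up` and
  `ccrcc1and4_up`; ccrcc4 raises `ccrcc4_up`, `t_effector` and
  `ccrcc1and4_up`; ccrcc3 is "low everything" — `ccrcc3_up` up,
  `ccrcc3_down`, `ccrcc2_up`, `cell_cycle`, `t_effector` down.
* **Proportions** default to (ccrcc1, ccrcc2, ccrcc3, ccrcc4) =
  (0.24, 0.40, 0.20, 0.16): the distribution the percentile tree itself
  induces when ccrcc3 fills its 20% quota, i.e. the reference distribution
  the percentiles were calibrated to reproduce. Class sizes are allocated
  deterministically by largest remainder and shuffled, so realized
  proportions match the spec exactly.
* **Batch effects** multiply each gene's mean by the batch's fold or its
  reciprocal (per-gene random sign). A sign-free uniform fold would be a
  pure library-size effect and would vanish in size-factor normalization;
  the random sign plants genuine per-gene batch structure for the
  correction to remove.
* `simulate_scores()` generates score matrices directly: `tie_free_uniform`
  (iid continuous scores — ties have probability 0),
  `four_centroid` (archetype centroids `separation` SDs apart, with true
  labels attached), and `adversarial_no_ccrcc3`, which hands the top
  T-effector values to the samples in the top quintile of the ccrcc3
  ratio, so the ccrcc3 conjunction is unsatisfiable by construction.

**What a green test does and does not establish.** The generator emulates
planted mean shifts, NB count noise and multiplicative batch effects. It
does not emulate FFPE degradation, gene-length or GC bias, correlated
gene modules beyond the planted signatures, outlier samples, or cohorts
whose composition departs from the reference proportions. Recovery of
planted truth at 4 SD separation (MCC ≥ 0.9 in the tests) therefore
demonstrates internal consistency of the pipeline, not clinical accuracy
on real tumors.

## Known limitations

* Percentile (cohort) mode is composition-dependent by design; fixed
  cutoffs transfer only under closely matched preprocessing.
* The empirical-Bayes batch correction under-corrects gene-specific batch
  deviations (see above) and assumes no batch/biology confounding; the
  generator assigns batches independently of subtype for exactly that
  reason.
* Signature gene lists must be supplied by the user (GMT or two-column
  TSV); the package ships no gene lists of its own, and accepts any
  symbol namespace as long as matrix and signatures agree
  (case-insensitive).
* The SVM is trained on decision-tree labels; it inherits any
  composition bias of the cohort it was trained on, and its confidence
  values are calibrated pairwise probabilities, not posterior subtype
  frequencies in any population.
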