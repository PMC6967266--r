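---
title: "Consensus biomarker discovery across expression cohorts: methods and design"
author: "hccpanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus biomarker discovery across expression cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hccpanel)
```

# The problem and the model

Tumor/non-tumor differential-expression results transfer poorly between
profiling platforms: probe chemistry, normalization and cohort composition
all shift which genes reach significance in any single study. `hccpanel`
treats replication across cohorts as the primary evidence. Its statistical
model is deliberately simple:

1. **Per-cohort testing.** Within each cohort, each gene is tested
   two-sided for a tumor vs non-tumor location difference — Welch's
   unequal-variance *t* for unpaired designs, the paired Wilcoxon
   signed-rank test when tumor/adjacent-normal pairing metadata is present.
   No cross-cohort pooling of expression values ever occurs, which is what
   makes the procedure platform-independent: only each cohort's own
   within-cohort contrast is used.
2. **Family-wise control per cohort.** Raw p-values are Bonferroni-adjusted
   with *m* = the number of genes tested in that cohort (the common-gene
   intersection in a pipeline run). Bonferroni rather than FDR keeps the
   per-cohort claim strong, which matters because the consensus step counts
   votes rather than effect sizes.
3. **Consensus vote counting.** A gene is a *core gene* when its adjusted
   p < `alpha` in at least `minSigFrac` of cohorts (threshold inclusive).
   Direction votes are counted over **all** cohorts — significant or not —
   so the up/down tallies always sum to the cohort count; the consensus
   regulation is the all-cohort majority, with exact ties resolved by the
   majority among significant cohorts only. When those two majorities
   disagree the row is flagged (`conflict`) instead of silently relabelled.
4. **Panel construction on one training cohort** (stumps → shortlist →
   wrapper → classifiers), described below.
5. **Survival screening** of panel genes by mean-dichotomization,
   log-rank, and Cox proportional-hazards models.

The implicit assumptions: log-scale expression is approximately
location-shifted between classes within a cohort; cohorts are exchangeable
votes (no weighting by size or quality); and a biomarker worth keeping
should replicate in most cohorts rather than average out well.

# Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `alpha` | 0.01 | — | per-cohort Bonferroni-adjusted significance level |
| `minSigFrac` | 0.80 | fraction | inclusive cohort fraction for core genes |
| `k10`, `k5` | 10, 5 | genes | sizes of the two shortlist stages |
| `panelSize` | 3 | genes | wrapper target |
| `wrapperFamily` | logistic regression | — | model scored during elimination |
| CV folds | 10 | — | stratified, fixed seed |
| decision threshold | 0.5 | probability | class calls in external evaluation |
| survival cut | mean | log2 units | high = strictly greater than cohort mean |

The defaults are the reference workflow's operating point; every one is
overridable through `pipelineConfig()`. The 80% rule is inclusive ("at
least"): over 27 cohorts, 22/27 = 81.48% qualifies while 21/27 = 77.78%
does not.

# Single-gene stumps and the metric suite

A stump for an up-regulated gene calls a sample cancer when expression is
strictly above its threshold; for a down-regulated gene, strictly below.
Samples exactly at the threshold always fall on the normal side. Candidate
thresholds are the midpoints of consecutive sorted unique training values
plus finite sentinels one unit below the minimum and above the maximum
(the all-cancer and no-cancer rules). This grid is complete: every
achievable confusion matrix of the stump family appears in it, so the
search is exhaustive rather than heuristic, and the unit tests compare it
against an independent brute-force oracle.

The optimization criterion is training **accuracy**; exact accuracy ties
are broken by higher MCC, then by the lower threshold, then direction up.
Accuracy is the natural criterion for the near-balanced training cohorts
this workflow targets; MCC as first tie-break guards against degenerate
majority-class solutions when classes are less balanced. AUROC for a
single gene is computed from the direction-oriented **raw expression**,
not from the binary stump output — a binary predictor's AUROC is capped by
its sensitivity/specificity pair, and single genes are plainly stronger as
continuous markers.

Degenerate inputs: a constant gene yields a flagged majority-class stump;
a confusion matrix with a zero MCC denominator factor scores MCC = 0 by
convention; reconstruction of counts from printed percentages rounds half
away from zero, and printed percentages are reproduced with half-up
rounding to two decimals (base R's banker's rounding would print 96.295 as
96.29 rather than the conventional 96.30).

# Shortlist, wrapper and classifiers

The `k10` best-ranked genes are re-scored by mean stratified 10-fold CV
stump accuracy (guarding against training-set overfitting of the
threshold), and the best `k5` enter backward elimination. At each wrapper
step, every leave-one-out subset is refit and scored by mean 10-fold CV
AUROC with the same fold assignment, and the best subset is kept; all
evaluated subsets are returned in an audit log so the selection can be
replayed. Exact score ties are frequent once AUROC saturates at 1.0 on
well-separated panels; since features arrive ranked best-first, a tie
removes the lowest-ranked feature. The wrapper's model family defaults to
logistic regression — the cheapest family whose CV score responds
smoothly to feature removal; the choice is exposed as a flag.

The six classifier families are trained with small, fixed grids searched
by mean 10-fold CV AUROC: 100/500 trees for the two forests; k ∈
{3, 5, 7, 11} for KNN; ridge penalty λ ∈ {0.01, 0.1, 1, 10} for logistic
regression (an explicit L2 penalty makes the regularization grid
meaningful and keeps separable panels numerically stable); C ∈
{0.1, 1, 10} × γ ∈ {1/(p·mean var), 0.01, 0.1} for the RBF SVC; Gaussian
naive Bayes has no grid. Grid ties keep the earliest (simplest) point.
External evaluation reports the threshold-dependent suite at tumor
probability > 0.5 plus AUROC with a stratified-bootstrap 95% CI (2,000
resamples by default).

Validation cohorts are only ever touched by the evaluation stage; the
pipeline's structure makes earlier access impossible, and the stage log
records the order of execution.

# Preprocessing choices

- Probe-to-gene aggregation is the arithmetic mean of a gene's probe rows;
  unmapped probes are dropped, gene order is lexicographic.
- RNA-seq FPKM values are transformed as log2(x + 1). The pseudocount of 1
  is the standard zero-safe choice.
- Quantile normalization (delegated to `limma::normalizeQuantiles`,
  ties averaged) is applied **per cohort after aggregation**, never jointly
  across cohorts — joint normalization would leak information between
  cohorts and break platform independence. Whether normalization precedes
  or follows aggregation is not uniquely determined by practice; the
  package normalizes the gene-level matrix, and `quantileNormalize()` can
  equally be applied probe-level before `aggregateProbes()` by callers who
  prefer that order.
- Gene symbols are matched exactly and case-sensitively; no alias
  resolution is attempted.

# Differential-test details

The Wilcoxon signed-rank test is implemented in-package: zero differences
are dropped; for n ≤ 25 remaining pairs the exact null distribution of the
positive-rank sum is built by dynamic programming over doubled ranks,
which stays valid under tied ranks (where `stats::wilcox.test` refuses an
exact p); above 25 a normal approximation with tie correction and
continuity correction is used, matching `wilcox.test(exact = FALSE,
correct = TRUE)` on tie-free data. Welch's test wraps `stats::t.test`,
with a vectorized row-wise version for whole matrices (tested against a
`t.test` loop). Degenerate genes: both groups constant and equal gives
p = 1 (never significant); constant but unequal gives p = 0 as the
limiting case. The paired/unpaired choice follows the pairing metadata
and can be overridden per cohort.

# The simulator: what it emulates and what it does not

`simulateCohorts()` emulates the post-preprocessing stage of a
multi-cohort study: per-gene baselines μ_g ~ Uniform(4, 12) on the log2
scale (the magnitude range of real training-cohort gene means), Gaussian
noise (sd 1), cohort-specific per-gene platform offsets (sd 1), planted
up/down genes adding ±`effectSize` to tumor means in a
`consistency`-fraction of cohorts chosen deterministically from the seed,
and a fraction of cohorts generated as paired designs with shared
per-patient intercepts (sd = noise sd), which is exactly the structure the
paired test exploits. The default study conditions are 10 cohorts of
40 + 40 samples, 1,000 genes, 10 + 10 planted genes at effect size 3 with
consistency 0.9 — cohort sizes inside the range of real HCC cohorts and
an effect size typical of the strongest replicated HCC genes (mean log2
differences of 3.5–5.4 in the reference training data).

The simulator does **not** emulate probe-level array physics, sequencing
counts or length biases, correlated gene modules, tumor purity gradients,
or batch structure within a cohort. Passing recovery tests therefore
demonstrates that the pipeline's logic is correct and well-calibrated
under its own model — independent cohorts, additive platform shifts,
Gaussian noise — not that real cohorts will yield panels of equal quality.
`simulateSurvival()` draws exponential event times with hazard
baseline × exp(Σ logHR × centered expression) and independent exponential
censoring calibrated to the requested censoring fraction (exact under the
null, approximate otherwise), capped at an administrative follow-up limit;
clinical covariates (age, gender, stage) are generated as nulls.

# Survival analysis conventions

Dichotomization is strictly-greater-than-the-mean, computed over the
patients present in the survival table (not the full expression cohort);
ties fall to the low group. Cox models use Efron tie handling, the
standard default of the R survival ecosystem. Multivariate models
optionally screen to univariate-significant variables (p < 0.05) first,
mirroring the usual two-stage clinical workflow; collinear covariates are
rejected by name, and monotone-likelihood non-convergence is flagged with
an infinite-bound CI rather than an error. Stage is treated as a single
ordinal 1–4 covariate so one hazard ratio per cohort is reported.

# Numerical and testing choices

Quantile-normalization idempotency is asserted to 1e-9; log-rank vs Cox
score-test agreement to 1e-6 on tie-free data; stump and AUROC
implementations are compared with brute-force oracles to machine
precision. The test suite exercises the simulation-recovery claims at
problem sizes chosen to keep the full suite in the low minutes on one
core: 50 replicates of the 10 × 1,000-gene consensus recovery, 20
end-to-end pipeline replicates (wrapper family logistic regression), 200
null replicates for type-I-error checks of the paired test, the log-rank
test and univariate Cox, and n = 500 with 30% censoring for hazard-ratio
recovery. Unit tests use smaller fixtures built in code.

# Known limitations

- Vote counting discards effect sizes; a gene just missing `alpha` in many
  cohorts gets no partial credit (no random-effects meta-analysis).
- Bonferroni with per-cohort *m* is conservative for large gene sets.
- The wrapper is greedy: it never revisits a removed feature, and with
  saturated AUROC its tie-breaking, not the data, decides among equally
  perfect subsets.
- KNN class probabilities from vote fractions are coarse (k ≤ 11), which
  flattens its ROC curves relative to the other families.
- The per-unit hazard-ratio interpretation of Cox fits depends on the
  expression scale; panel screening therefore reports the dichotomized
  high-vs-low hazard ratio instead.
- The package starts from log-scale matrices: raw CEL/idat preprocessing,
  identifier alias resolution and enrichment analysis are out of scope.
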