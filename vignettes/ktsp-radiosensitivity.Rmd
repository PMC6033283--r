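---
title: "Rank-based single-sample predictors of radiotherapy response: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-based single-sample predictors of radiotherapy response: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radSSP)
```

## The problem

After breast-conserving surgery, adjuvant radiotherapy (RT) roughly halves
the rate of ipsilateral breast tumor recurrence (IBTR), but the benefit is
far from uniform: some patients would remain recurrence-free without RT,
while others recur despite it. A gene-expression classifier that works on a
targeted panel — robust enough for degraded RNA and single samples — could
stratify patients into those who can be spared RT, those who should receive
it, and those who are intrinsically radioresistant and need something more.

`radSSP` implements such a workflow end to end on a 248-gene
NanoString-nCounter-style panel: quality filtering and control-probe
normalization of raw counts, k-top-scoring-pairs (k-TSP) single-sample
predictors (SSPs) of IBTR trained per estrogen-receptor (ER) × RT stratum,
signature scoring, survival evaluation, and the consecutive-classifier
treatment stratification. Because the real tumor cohorts cannot be shipped,
a synthetic cohort generator reproduces the *structure* of such a study and
makes every stage testable.

## The classifier

A k-TSP SSP is an ordered list of k gene pairs. Each rule is of the form
*expression(gene A) > expression(gene B)*, evaluated entirely within one
sample; a rule that fires votes "high risk", and the unweighted majority of
the k votes classifies the sample. The vote fraction serves as the model's
raw continuous score. Because only within-sample ordering is consulted, the
prediction is invariant to any strictly monotone per-sample transform of
the expression values — the property that makes SSPs portable across
platforms and normalization schemes.

Training ranks every gene pair by the score
$\Delta_{ij} = |\hat P(X_i > X_j \mid \text{case}) - \hat P(X_i > X_j \mid \text{control})|$,
with a within-sample tie $X_i = X_j$ counting 1/2 toward each probability.
Ties in $\Delta$ are broken by $\gamma_{ij}$, the absolute between-class
difference of the mean within-sample rank difference (ranks taken over the
whole analysis gene set), and finally lexicographically by gene id for full
determinism. Pairs are selected greedily under gene disjointness, the pair
oriented so that *A > B* points at the high-risk class. The number of pairs
k is chosen by stratified cross-validation over a grid of odd values,
maximizing mean balanced accuracy, ties going to the smaller k.

Numerical notes, all deliberate:

* **Tie handling.** Counting expression ties as 1/2 preserves the symmetry
  $\Delta(i,j) = \Delta(j,i)$; a tied rule likewise contributes half a vote
  at prediction time.
* **Odd k.** The grid contains odd values only (default 101, 103, … up to
  half the gene count), so a tie-free majority vote is always decisive. The
  training floor of 100 pairs is rounded up to 101; with at least 100
  disjoint pairs every model spans at least 200 distinct genes.
* **Balanced accuracy** is the cross-validation criterion because the
  case/control design deliberately over-samples recurrences.
* **Sorting keys are rounded to 10 significant digits** before ranking
  pairs. Mathematically tied $\Delta$ or $\gamma$ values can differ by one
  ulp depending on floating-point summation order, which would otherwise
  let noise decide lexicographic ties. Genuine score differences on any
  realistic cohort are many orders of magnitude larger than the rounding.
* **Small-stratum guard.** Strata with fewer than 10 cases or 10 controls
  (configurable) are refused at training and skipped at pipeline level —
  the fate of the tiny ER-RT- stratum in the emulated design.
* **Missing genes.** Prediction refuses silently incomplete data; porting a
  model to a platform lacking genes is an explicit `subset_model()` call
  that drops the affected rules (plus, if needed, the lowest-ranked rule to
  restore odd k) and records them in the model metadata.

## Normalization

Raw counts pass three fixed steps: per-sample scaling to equalize
positive-control geometric means, per-sample scaling to equalize
housekeeping geometric means, then `log2(x + 1)`. The across-sample target
of each scaling step is the *geometric* mean of the per-sample geometric
means. With an arithmetic target the two steps do not compose idempotently
(re-normalizing normalized data multiplies everything by
$\overline{b}\,\overline{1/b} > 1$); with the geometric target
re-normalization is exactly the identity, which the test suite asserts to
1e-9. Since both steps are uniform per-sample rescalings, they never change
within-sample gene order, so k-TSP predictions are independent of them — also
asserted as an invariant. A geometric mean over a set containing zero is
defined as zero and routed to the QC error path rather than patched with
pseudocounts.

Quality control mirrors standard nCounter practice (the emulated study
reports only the outcome of its filtering, not its thresholds, so the
defaults here are conventional and configurable): a sample fails when its
positive-control scale factor leaves [1/3, 3] or its housekeeping geometric
mean drops below 32 counts; an endogenous probe fails when it sits at or
below the sample background (mean negative control + 2 SD) in at least 85%
of samples.

## The synthetic cohort generator

The generator defines the study conditions; its defaults are fixed, not
tuning knobs.

* **Design.** 172 discovery + 164 validation samples; stratum frequencies
  ER+RT+ 0.55, ER+RT- 0.22, ER-RT+ 0.21, ER-RT- 0.02, mirroring the ER/RT
  margins of the emulated case-control series and leaving ER-RT- with ~3
  validation samples on purpose, to exercise the small-stratum guard; 40%
  IBTR cases per stratum, matching the enrichment of the emulated cohorts.
* **Counts.** Endogenous counts are negative binomial (dispersion 0.1) with
  gene baseline means spread over $2^{[4,10]}$ and a lognormal per-sample
  size factor (log-sd 0.2) — the standard count model for nCounter-like
  data. Housekeeping probes get high baselines ($2^{[11,13]}$) and no class
  effect; positive controls follow a fixed 4-fold geometric titration
  ladder with Poisson noise; negative controls are Poisson with mean 2.
* **Planted signal.** Each stratum receives `n_planted_pairs` (default 10)
  disjoint gene pairs. A pair occupies its own mean band (6-fold gap within
  the pair, 6-fold separation between bands, bands cycling after five, all
  bands above the background-gene mean range); within a pair the two levels
  are swapped between samples with class-dependent probability
  $\tfrac12 \pm \texttt{planted\_delta}/2$. The signal is therefore purely
  order-based — exactly the quantity k-TSP detects — and confined to the
  designated pairs: comparisons across bands, or against background genes,
  are class-independent by construction. Without banding, cross-pair
  combinations of planted genes would carry the same ordering signal as the
  pairs themselves and the planted pairs would not be identifiable.
* **Survival.** Cases draw exponential event times (median 4.4 years);
  each control is censored at a time uniform between a randomly matched
  case's event time and 25 years, mirroring a design in which controls must
  remain recurrence-free at least as long as their matched case's time to
  recurrence. The matching ratio of the original design is not fully
  specified anywhere, so the generator works with stratum-level frequencies
  instead of explicit 1:k matching.

What the generator does *not* emulate: the gene-gene correlation structure
of real tumors, FFPE/RNA-degradation artifacts, platform batch effects, or
a treatment assignment mechanism (RT is a stratum label, not an outcome of
indication). Passing tests on synthetic cohorts therefore demonstrate that
the machinery is correct and calibrated — recovery of planted order signal,
chance-level AUC and nominal test size under the null — not that the
classifiers would reach any particular performance on real tumors.

## Signature scores

* **Rank-linear score** (the 10-gene-signature surrogate family):
  coefficient-weighted sum of within-sample ranks. Rank scope defaults to
  the whole panel (configurable to the signature's own genes — the emulated
  study does not state which scope its surrogate used, so both are
  provided), direction ascending, average ranks for ties. The published
  surrogate's coefficients are not redistributed; a clearly labelled
  synthetic placeholder signature ships with the package and any
  `gene_id,coefficient` CSV can be supplied instead.
* **Proliferation / immune scores**: geometric means of linear-scale
  normalized expression of {MKI67, AURKA} and of ten immune-response genes.
  The functions refuse log-scale or non-positive input rather than
  guessing.
* **Median dichotomization** uses a strict cut (high iff score > median,
  exact median assigned low), computed over whatever sample set the caller
  passes — appropriate for cohorts deliberately enriched for events, where
  a population cutoff would be meaningless.
* **Score correlation**: Pearson r plus an OLS fit, p-value from the
  two-sided t test for zero slope on n − 2 degrees of freedom.

## Survival evaluation

Kaplan-Meier estimation, log-rank testing and Cox fitting delegate to the
`survival` package, ROC/AUC to `pROC` (the AUC equals the Mann-Whitney
concordance with ties counted 1/2); the package defines stable result
containers, input guards, and the reporting conventions on top. Cox models
use Breslow tie handling by default (Efron behind a flag), Wald 95%
intervals, and refuse fits with fewer than five events per coefficient,
constant covariates, or monotone likelihood. Cumulative risk at a horizon
(e.g. 10-year IBTR risk) is read off the Kaplan-Meier step function at the
last event time before the horizon. The test suite cross-checks these
wrappers against independent oracles: a hand product-limit computation, a
10,000-permutation null for the log-rank test (compared through the
permutation mid-p, the right comparator for a discrete null), and a
two-stage grid search of the written-out Breslow partial likelihood
agreeing with the Cox coefficient to 1e-4.

## Treatment stratification

Two locked SSPs are applied consecutively: samples called low-risk by the
RT-untrained model need no RT ("No-RT"; the second model is not evaluated
for them); of the rest, those called low-risk by the RT-trained model form
"Give-RT" and the remainder "More-treatment". The three groups partition
the input exactly and the assignment is a pure function of the two
predictions. Evaluation computes, per group, Kaplan-Meier curves split by
actual RT and a log-rank p for the RT effect — groups lacking an RT arm are
reported prognostic-only, as happens for ER- cohorts where almost everyone
received RT — plus one overall Cox model with group, RT and group×RT
interaction terms when it is estimable (with no RT effect in the generator,
separation in a small arm frequently makes it inestimable; the report then
carries the reason instead of a fit). The pipeline applies the scheme per
ER arm, pairing that arm's RT- and RT+ models, and refuses mismatched
model/sample ER status unless explicitly overridden.

## Reproducibility and problem sizes

Every stochastic step is seeded: the generator consumes `config$seed`, fold
assignment its own seed, and reruns of `run_pipeline()` under one
configuration are byte-identical, including the serialized report. Model
files are JSON containing rules and metadata only — never training data.

Simulation-based checks in the test suite and acceptance script run at
sizes chosen to estimate the relevant properties tightly while staying
desk-scale: 20-seed Monte-Carlo estimates for planted-pair ordering
differences and recovery (n = 200, 5 pairs), 20 null cohorts
(120 discovery / 80 validation) for AUC calibration with a reduced k grid
{11, 21, 41}, 40 null datasets for log-rank size, 200 random instances
(≤ 8 genes × ≤ 12 samples) for exhaustive-oracle equivalence, and 100
random monotone transforms for rank invariance. Thresholds for
seed-frequency checks (e.g. "at least 16 of 20 seeds") are set so that a
correctly calibrated method passes with high probability while gross
miscalibration still fails.

## Known limitations

* The synthetic validation says nothing about clinical performance; the
  headline numbers of any real application must come from real cohorts.
* The 10-gene surrogate ships with placeholder coefficients; results from
  it are exercises of the machinery, not of the published signature.
* The Cox interaction analysis assumes proportional hazards and enough
  events per arm; the case-control enrichment of the emulated design makes
  absolute risks and hazard ratios descriptive only.
* Whether the original k-TSP analyses allowed even k, or how they resolved
  tied majority votes, is not documented anywhere; this implementation
  enforces odd k and breaks the remaining half-vote ties toward low risk,
  and records both choices here rather than guessing at compatibility.
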