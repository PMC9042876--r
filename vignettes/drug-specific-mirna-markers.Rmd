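---
title: "Screening for drug-specific miRNA survival markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for drug-specific miRNA survival markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirdrugscreen)
```

## The problem

A biomarker that predicts survival *under a particular drug* is more useful
for treatment decisions than one that predicts survival of a cancer type in
general, but pooled-cohort analyses cannot distinguish the two. This
package screens for such markers by forming **cancer-drug groups** — all
patients of one cancer type exposed to one standardized drug — and testing
each miRNA's expression classes for survival separation inside each group,
while contrasting against the same test on the whole cancer cohort.

This vignette documents the statistical model, the parameters that matter,
the numerical conventions, and what the synthetic-data experiments do and
do not establish.

## Expression binarization

Survival stratification needs a two-class split of a continuous expression
value. The package fits, per feature, a one-step function to the sorted
pan-cohort expression vector: for each breakpoint $b \in \{1,\dots,n-1\}$
the fitted values are the means of the lower $b$ and upper $n-b$ sorted
values, and the $b$ minimizing the summed squared error is selected. The
class threshold is the midpoint of the two segment means.

Conventions, fixed for determinism:

* **Tie rule for SSE.** Duplicated expression values can make several
  breakpoints exactly optimal; ties (equality within a relative tolerance
  of $10^{-8}$, which absorbs floating-point jitter in the prefix-sum
  evaluation) resolve to the smallest breakpoint.
* **Threshold placement.** The midpoint of the adjacent segment means. The
  step-fitting literature does not pin the cut placement; the midpoint is
  symmetric, reproduces the fitted split exactly, and is equivariant under
  affine rescaling of the data.
* **Class rule.** `high` strictly above the threshold, `low` at or below;
  a value exactly at the threshold is therefore `low`.
* **Two classes only.** Some step-fitting variants insert an
  "intermediate" margin around the step; the screening protocol here is a
  strict two-class design, so no margin is used.
* **Missing values** are excluded from the fit (`n_used` records how many
  values contributed) and stay unlabeled in class assignment, so a patient
  with a missing value is counted in neither class for that feature.
* **Degenerate features** (fewer than two distinct non-missing values)
  admit no step; they raise a `no_valid_threshold` condition and are
  excluded upstream with a log entry.

The threshold is fitted **globally** — on all patients across all cancer
types — not per group. A global threshold defines "high expression" on a
platform-consistent scale; per-group refits would let the same expression
value be "high" in one group and "low" in another.

## The screen

Groups require at least `min_group_size = 15` eligible patients (clinical
record, standardized drug exposure, expression profile); patients belong to
every group they qualify for; duplicate treatment records of one drug count
once. Within a group, a feature is tested only if both classes hold at
least `min_class_size = 5` patients — smaller classes make the log-rank
approximation unreliable and are recorded as gated, not tested.

The test is the standard unweighted log-rank statistic with a chi-square
(1 df) reference. Ties follow the standard convention: subjects censored at
time $t$ remain at risk for events at $t$. With zero events in both groups
the statistic is undefined and the result is flagged with $p = 1$.
Kaplan-Meier estimation and the log-rank test are computed through the
`survival` package; the test suite re-derives both against hand-coded
product-limit and hypergeometric oracles.

**FDR scope.** Benjamini-Hochberg adjustment is applied within each group
across its tested features (`fdr_scope = "per_group"`, the default),
matching per-group marker reporting; a single global adjustment across all
(feature, group) pairs is available via `fdr_scope = "global"`. Markers
require adjusted values below `mirna_fdr = 0.1`.

**Drug specificity.** For each cancer type the identical screen (same
global thresholds, same gate) runs on all patients of that cancer with
expression data — including patients without drug records, since the
contrast population is the cancer type, not the union of groups. A
group-significant feature is drug-specific when its cancer-wide
BH-adjusted value is at or above the same 0.1 threshold
(`cancer_specificity_mode = "adjusted"`). Whether the contrast should use
adjusted or raw cancer-wide p-values is genuinely open; the raw-p variant
is exposed as `mode = "raw"` with `cancer_alpha`. A feature gated
cancer-wide would count as not significant cancer-wide; in practice the
group population is a subset of the cancer population, so a feature tested
in a group is never gated cancer-wide — the branch exists for robustness.

**Survival direction.** Which class "survives better" is decided by
restricted mean survival time — the area under each class's Kaplan-Meier
curve up to the shorter class's last observed time. Unlike median survival
(undefined under heavy censoring) or the sign of observed-minus-expected
(opaque to users), RMST is always defined on the common follow-up window.
Exact ties resolve to `low`.

## Target genes and concordance

Target genes of the drug-specific miRNAs — from user-supplied pair tables,
de-duplicated across sources with regulation conflicts demoted to
`unknown` — are screened with the same machinery at the stricter
`gene_fdr = 0.01`, with BH applied within each group across the target
genes tested there (mirroring the miRNA scope; configurable). Each
(drug-specific miRNA, significant target gene) pair in one group forms one
combination; a gene targeted by two marker miRNAs contributes twice.

For each combination, the gene's expression is regressed on the miRNA's
expression by ordinary least squares **over the group's patients**: the
combination is a claim about that group's context, so pan-cohort
correlation would conflate between-group structure with the within-group
relationship. Combinations with slope p-values at or above
`corr_alpha = 0.05` are flagged but retained.

The consistency verdict compares regulation sign with survival directions:
an inhibitory pair is consistent when the directions are opposite, an
activating pair when they agree, and unknown regulation (or an undefined
direction) yields `unknown`. The rule is invariant under flipping both
directions simultaneously, which the test suite asserts exhaustively.

## External validation

Thresholds learned on the discovery platform do not transfer to microarray
scales, so validation cohorts are split at the **within-cohort median** of
each marker; the log-rank test and RMST direction then proceed as in the
discovery screen. Any `(time, event)` endpoint — overall, disease-free, or
distant-relapse-free survival — is handled identically; the endpoint label
is metadata. Markers absent from a cohort's expression matrix are reported
as unavailable rather than failing the run.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the screen assumes,
not the marginal distributions of any real cohort:

* Planted marker miRNAs are two-component Gaussian mixtures
  (`low_mean = 2`, `high_mean = 6`, `sd = 1`, `high_fraction = 0.5` by
  default, i.e. 4-sd class separation); null miRNAs are unimodal Gaussians
  at the midpoint.
* Survival is exponential with hazard
  $\lambda = \lambda_0 \cdot \mathrm{HR}^{z}$, where $z$ is the patient's
  high-class indicator, applied only to patients inside the planted
  (cancer, drug) group; censoring is independent exponential and the event
  indicator marks whether death came first. Defaults
  $\lambda_0 = 10^{-3}$/day (median survival around two years) and
  censoring rate $2.5 \times 10^{-4}$/day (roughly 80% of deaths observed)
  are plausible for an aggressive-cancer cohort with long follow-up. The
  proportional-hazards exponential model is the simplest generator
  consistent with a log-rank screen. An optional administrative follow-up
  cap (`max_follow_up`, default none) censors everyone still at risk at a
  fixed study-end time, as real cohorts do.
* Drug exposure draws a **fixed-count** random subset per (cancer, drug):
  `round(patients_per_cancer * drug_exposure_prob)` patients sampled
  without replacement, independently per drug, so patients can belong to
  several groups while group sizes are exact. Exact sizes make the power
  experiments below realize their stated group sizes precisely, at no cost
  to the multi-membership structure.
* Planted target genes are decreasing affine functions of their miRNA
  (slope −1) plus Gaussian noise at half the expression `sd`, emitted as
  `inhibit` pairs; remaining genes are null and paired to random miRNAs
  with `unknown` regulation as decoys.
* One seed drives everything; identical configurations are byte-identical.

What passing tests on this generator do **not** show: robustness to
batch effects, non-proportional hazards, informative censoring, skewed or
zero-inflated expression, or realistic cancer-type frequencies — none of
which the generator emulates.

## Study designs used by the tests and acceptance script

Problem sizes were chosen as design decisions, with a pre-registered power
analysis, and are stated here so results can be read correctly:

* **Marker recovery.** One cancer type of 3,200 patients; one drug exposing
  exactly 40 (a 1.25% exposure fraction, so the cancer-wide contrast stays
  quiet); hazard ratio 4 for the high class; 6-sd bimodal separation
  (means 2 and 8) so that class labels recover the latent mixture nearly
  perfectly at n = 40; a panel of 4 miRNAs (1 planted + 3 null); censoring
  rate $2 \times 10^{-5}$/day. Measured over 80 seeds, about 93% of seeds
  recover the planted marker as group-significant (FDR < 0.1) *and*
  drug-specific; the residual failures are genuine log-rank tail draws at
  n = 40 and occasional chance cancer-wide significance — the intrinsic
  operating characteristic of these conditions, not a software artifact.
* **Null calibration.** Hazard-ratio-1 cohorts with 500 null miRNAs and a
  40-patient group: discoveries at FDR < 0.1 average well under one per
  500 features per seed, and the unadjusted screen p-values are uniform by
  a Kolmogorov-Smirnov check at 1,000 features.
* **End-to-end concordance.** One cancer of 4,000 patients, 60 exposed, a
  protective planted miRNA (hazard ratio 0.25) with two inhibitory targets.
  The protective case needs the heavier default censoring: long-lived
  protected patients otherwise dominate late risk sets and make even a
  60-of-4,000 subgroup visible cancer-wide.
* **Validation calibration.** 400 null cohorts of 100 patients each,
  median-split and log-rank tested; the empirical type-I error at
  $\alpha = 0.05$ sits within a few points of nominal.

## Known limitations

* The drug-name standardization ships as a mechanism (normalize, then look
  up a user-supplied raw-to-canonical table); no curated drug-name list is
  bundled.
* No Cox regression, stratified or weighted log-rank variants, and no
  interaction test between drug and expression: drug specificity is defined
  by the two-screen contrast only.
* BH adjustment is not idempotent (no step-up adjustment is); adjusted
  values should never be re-adjusted.
* The single-step binarization assumes essentially bimodal (or
  monotone-shifted) expression; features with more structure get a
  least-squares compromise threshold.
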