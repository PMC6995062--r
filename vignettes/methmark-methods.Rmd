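---
title: "Methods: multi-cohort CpG marker discovery in methmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-cohort CpG marker discovery in methmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methmark)
```

## The model

A blood-based tumor methylation marker must separate three signals: the
target cancer's primary tumors (highly methylated), all normal and
non-target tissue (unmethylated), and peripheral blood (almost
perfectly unmethylated, because plasma cell-free DNA is overwhelmingly
hematopoietic). `methmark` operationalises this as a filter grammar
over binned beta values rather than as a parametric test: each probe ×
(cohort, subset) group is summarised by the percentage of samples in
each methylation bin, and candidate markers are the probes whose
percentages clear a conjunctive chain of thresholds.

The bins partition [0, 1] with closed upper bounds: UM (β ≤ 0.15),
IM (0.15 < β ≤ 0.3), LM (0.3 < β ≤ 0.6), HM (β > 0.6). Boundary
membership is exact — 0.15 is UM, 0.3 is IM, 0.6 is LM — with no
epsilon slack, because the inequalities are unambiguous; the acceptance
suite checks a 10⁻⁴ grid of [0, 1] against an independent conditional
oracle.

## Percentages, missingness, small groups

Percentages are computed in double precision as 100·count/n_eval over
the **non-missing** samples of a group; probes with some missing betas
are not excluded wholesale. Whether the original analyses used
non-missing denominators or dropped incomplete probes is not
documented anywhere we could rely on, so the non-missing-denominator
policy is our explicit choice. Groups with fewer than `min_n`
(default 5) evaluable samples are reported as unevaluable (`NA`),
never as 0 — a probe with three informative blood samples cannot be
certified 98% unmethylated in blood.

How unevaluable groups interact with filters is a policy of the chain:

- `fail_probe` (default): a probe unevaluable in any referenced group
  fails that criterion. Conservative, appropriate for certification.
- `skip_group`: unevaluable cohorts are dropped from both numerator
  and denominator of a cross-cohort mean; a criterion with no
  evaluable group left fails.

## The filter grammar

A criterion is V_P(C, S) ⋛ n with V one of the six metrics, C either a
named cohort or "all cohorts except the target", S a subset label, and
n ∈ [0, 100]. Cross-cohort criteria support two readings: the
unweighted **mean over cohorts** (the default — "Average (%UM)" reads
most naturally as a mean of per-cohort percentages, not a pooled-sample
percentage, which would let one large cohort dominate) and the stricter
**every cohort** reading, selectable per criterion. Thresholds are
compared at full precision; percentages are never rounded first.

The breast-cancer preset is the five-filter chain with thresholds
30 / 40 / 40 / 40 / 98. Metastasis and immune-cell subsets are not
referenced by the preset but remain addressable by custom criteria.
Which non-target cohorts enter the cross-cohort means is fully
determined by the metric table the user supplies, so the cohort roster
is configurable rather than hard-wired.

## Stratified enrichment

For a candidate probe, target PTs are stratified by beta into
H (β ≥ mean + 1σ) and L (β ≤ mean − 1σ), using the sample standard
deviation (n − 1 denominator; population vs sample SD is unspecified in
the source analyses, and at the relevant group sizes the difference is
negligible). Bounds are inclusive; a tolerance of 10⁻¹⁰ absorbs the
floating-point rounding of mean ± σ so that a sample lying exactly on
the boundary joins its subset. A zero-variance group yields empty H and
L rather than "all samples qualify".

Genes are ranked by the signal-to-noise statistic
(mean_H − mean_L)/(sd_H + sd_L), each class SD floored at 0.2 × |class
mean| — the canonical convention of the cited enrichment methodology.
Ties are broken by gene id in C-locale lexicographic order so the
ranking is strictly deterministic. With fewer than 7 samples per class
the SD floor dominates the statistic; a warning suggests the
t-statistic alternative. Genes missing in more than 20% of H ∪ L
samples are dropped; the remainder are mean-imputed within the pooled
samples before computing class statistics.

The enrichment score is the weighted Kolmogorov–Smirnov running sum:
hits advance by |s|^p normalised by the hit total, misses retreat by
1/(N − N_hit), and ES is the signed maximum deviation. With p = 0 this
is exactly the classic two-sample KS statistic on rank positions, a
reduction the tests verify. If every hit statistic is zero at p > 0
(degenerate but possible), hits fall back to equal weights rather than
dividing by zero.

The null is **phenotype permutation**: H/L labels are reshuffled within
the pooled samples (class sizes preserved), the ranking recomputed,
and ES re-scored. The enrichment settings — signal-to-noise ranking,
weight p = 1, phenotype permutation, 1000 permutations — are the cited
method's canonical defaults; the source analyses do not record which
settings they used, so ours are documented choices, all configurable.
NES divides ES by the mean |permuted ES| of matching sign; the nominal
p is the fraction of same-sign permuted ES at least as extreme; the
FDR q is the sign-stratified ratio of the permuted-NES tail fraction
to the observed-NES tail fraction, capped at 1. For pools of ≤ 8
samples an `exhaustive = TRUE` mode enumerates all label partitions,
and the tests require exact agreement with an independent enumeration
oracle there. A gene-permutation null is deliberately not offered.

## Covariate association

Group comparisons of beta by stage, subtype, race or ethnicity use a
seeded permutation test on the difference of group means (10,000
permutations by default) rather than a normality assumption — beta
values are bounded fractions, and the original comparisons were made
interactively in a point-and-click statistics package without a named
test. All pairwise p-values are Benjamini–Hochberg adjusted, stated in
the output. Stage is reported in natural order I–IV (IV is retained
when present even though typical reports stop at III); subtype in the
order Basal, LumA, LumB, HER2. Age uses a simple linear regression of
beta on age, reporting R². Levels below `min_n` are reported but
flagged and excluded from pairwise tests, never silently dropped.
Correlations with expression use pairwise-complete deletion.

## The synthetic generator

`generate_cohorts()` emulates the structure the pipeline assumes: a
target cohort with PT and SN subsets, several other tumor cohorts with
PT and SN, and one peripheral-blood cohort. Per (probe class, cohort,
subset), betas are drawn from beta distributions parameterised by
(mean, concentration) — the natural noise family for fractions, in
preference to truncated Gaussians. Defaults:

- target roster: target 60 PT + 40 SN; five other cohorts 40 PT +
  30 SN; 100 blood samples — seconds-scale while keeping binomial
  noise on percentages small;
- markers: target-PT mean 0.7 (conc 25), unmethylated state mean 0.08
  (conc 25), blood mean 0.01 (conc 40);
- five decoy classes, three probes each, engineered to violate exactly
  one preset filter apiece;
- 100 background probes with a cohort-shared baseline mean uniform on
  [0.05, 0.95] (conc 10).

Concentrations were chosen once, from the beta-binomial tail
probabilities, so that planted pass/fail margins are decisive at the
default sample sizes (e.g. the blood state gives P(β > 0.15) ≈ 2×10⁻⁴,
so %UM ≥ 98 holds with probability ≈ 1 − 2×10⁻⁶ at n = 100). No
quantitative within-cohort beta distribution is available to match, so
these shapes are chosen for test power, not biological fidelity.

Covariate structure: marker probes in target PTs get an additive mean
shift of +0.04 per stage above I (monotone I < II < III, mirroring the
reported stage trend) and subtype shifts with Basal lowest (−0.08;
LumB/HER2 +0.05). Age, race and ethnicity are drawn independently of
beta, so their associations are null by construction. Expression for
target PTs contains genes linearly linked to a marker's beta with
population correlation ρ (default 0.8 for 10 genes); the responsive
gene set collects those genes.

What the generator does **not** emulate: array batch effects and
cross-platform normalisation (all matrices are treated as directly
comparable, as the pipeline assumes of its real inputs), probe
cross-reactivity, correlated CpG blocks, cellular-composition
heterogeneity, and cfDNA fragmentation. Passing tests therefore
demonstrate the pipeline's correctness and statistical calibration,
not that real TCGA/GEO data would yield any particular marker count.

## Determinism and seeds

A single run seed fans out into per-stage child seeds derived from the
stage name, so any stage can be rerun in isolation with the same
stream. Rerunning the demo with the same seed is byte-identical across
all analytic outputs (the run log and timing manifest are excluded).
Problem sizes used by the test suite and acceptance script — 120
probes × 550 samples, 200 genes, 100–200 permutations, 20-seed sweeps —
were chosen to keep a full run in tens of seconds while leaving the
planted-signal margins decisive.

## Known limitations

- The filter grammar certifies marginal bin percentages only; it does
  not model covariance between cohorts or probes.
- FDR q-values from the sign-stratified ratio are coarse when few gene
  sets are tested; interpret them comparatively.
- The narrowing of filter-passing candidates to an assay panel
  (sequence context, cross-cancer specificity ranking) is intentionally
  out of scope: it was not algorithmically specified in the source
  analyses.
- Display conventions that center beta at 0.5 are rendering choices
  only; all computation stays on the [0, 1] scale.
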