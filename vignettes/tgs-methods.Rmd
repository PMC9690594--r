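---
title: "Total genotype scores for athlete cohorts: models, assumptions, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Total genotype scores for athlete cohorts: models, assumptions, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tgslift)
```

## The score model

A total genotype score (TGS) aggregates L biallelic loci. Each locus
contributes a genotype score in {0, 1, 2}: the "optimal" homozygote scores
2, the heterozygote always 1, the other homozygote 0. The individual TGS is
`100/(2L) × Σ score`, so it lives on a 0–100 scale regardless of panel
size. Two score tables are packaged: the 12-locus PWM, whose directions
come from the prior strength/power literature, and the 6-locus WRM, whose
loci and directions are data-driven (below). `tgs()` refuses to score
individuals with a missing genotype at any table locus rather than
prorating — a missing locus would silently shrink the score toward 0, and
the sample sizes here make exclusion cheap. Excluded individuals are
counted in the `n_missing` attribute.

## Collapsed genetic models and the association screen

For each locus the three genotype counts are collapsed into a 2-category
comparison: dominant (one homozygote vs the rest), recessive (that
homozygote plus the heterozygote vs the other homozygote), and allele
(2n allele counts). Which homozygote anchors the dominant model is a
per-locus convention stored with the panel: it follows the published count
table's row labels, under which ACTN3 alone pools the hi-allele carriers in
its dominant model. All comparisons use plain Pearson χ² with no continuity
correction — recomputing the published grid shows its highlighted p-values
(0.003, 0.007, 0.040, 0.043, 0.049) match uncorrected χ² only; Yates or
Fisher would not reproduce them. A degenerate table (a zero-margin
category) raises an error instead of silently dropping the column.

The Hardy–Weinberg test compares observed genotype counts against
p², 2pq, q² at the observed allele frequency, χ² with df = 1. On the
packaged counts it flags exactly CHRNB3 and TRHR in controls and ACE, CKM
and CNTFR in weightlifters — the same sets the discovery study reports.
Monomorphic input returns χ² = 0, p = 1 with a flag.

Bonferroni adjustment is reported with an explicit test count m
(`min(1, p·m)`), and the screen reports both m = 6 and m = 12 columns: the
study's discussion implies only the CNTFR association survives correction,
which is consistent with m = 6 (per-locus across models) but not m = 12, so
both conventions are surfaced rather than picking one silently.

## Building the WRM from the screen

`build_wrm()` selects every locus with any screened model at p < α (default
0.05, unadjusted — the published model includes loci at p = 0.043 and
0.049, which could not survive any multiple-testing correction, so
selection is deliberately on raw p-values with adjusted ones reported
alongside). The score direction is not stated as a rule in the source
material; the package uses: the allele with higher frequency in the
triggering case group than in controls defines the score-2 homozygote,
where the all-weightlifter group takes precedence over the international
group when both trigger. On the packaged counts this reproduces all six
published orientations, including the two flips against the literature
directions (ACE DD = 2, CHRNB3 GG = 2). Ties in allele frequency raise an
unresolved-direction error rather than guessing.

Why the screen uses dominant/recessive/allele: the methods text also
mentions a "genotype" (2×3) comparison, but only the three printed model
columns reproduce the published 6-locus selection from the printed
p-values, so the builder screens those three; the genotypic model remains
available in `collapse_counts()`.

## Group means, exact distributions, thresholds

Because the TGS is a sum, the group mean depends only on per-locus genotype
frequencies: `tgs_mean_from_counts()` recomputes the published control and
national-level WRM means (32.93 and 35.53) from marginal counts by
linearity of expectation. The published international mean prints as 38.60
but linearity over the printed international counts gives ≈ 38.06; the
package treats the two recoverable means as the checkable ones and leaves
the international value as a logged discrepancy (most plausibly a digit
transposition). Similarly the PWM group means (43.6/42.78/45.73) and all
published standard deviations involve within-person covariance across loci
that marginal counts cannot determine; they are not asserted anywhere.

`tgs_distribution()` goes one step further under an explicit independence
assumption: treating loci as independent draws from their marginal
frequencies, it convolves the per-locus score distributions into the exact
pmf of the integer score sum. The convolution mean equals the linearity
mean to 1e-10 (a structural identity used as a test), and the pmf is
validated against a 10⁶-draw Monte Carlo oracle (total variation < 0.005).
Threshold proportions such as P(TGS ≥ 50) follow from the pmf; the
published individual-level proportions (15.62% of controls, 28.36% of
international lifters at ≥ 50) depend on the true within-person correlation
of the six loci, which no count table can pin down, so the independence
values (≈ 16.4% for controls) are reported qualitatively and not asserted
against the printed ones.

## Group comparisons

The TGS group tests mirror the study's analysis plan: an unpaired
equal-variance t-test (Welch behind a flag — the source names only an
unpaired t-test, and with n = 416 vs 192 and similar spreads the pooled
version is the natural default), one-way ANOVA across the ordered groups,
and a linear-trend test over control < national < international. The trend
is fitted by least squares on centered, equally spaced group scores
(−1, 0, +1), which for equal group sizes is exactly the regression of the
values on the group index; this was chosen over the
contrast-with-within-group-MSE variant so that the regression identity
holds exactly rather than approximately, making the behaviour easy to pin
with an independent oracle. Performance analyses regress Wilks points on
TGS by OLS and compare performance between genotype groups with the same
machinery (two groups → pooled t; three → ANOVA). Wilks points are consumed
as given: no body-weight formula is computed.

## The synthetic generator

No individual-level data are distributable, so `simulate_study()` emulates
the cohort structure the analysis assumes:

* **Genotypes** — independent categorical draws per locus; each group draws
  at its own published genotype frequencies (`enrichment = TRUE`,
  reproducing the ordered TGS structure) or all groups draw at control
  frequencies (the null configuration used for calibration). An HWE mode
  draws at p², 2pq, q² from the group's allele frequency instead.
* **Performance** — Wilks points as
  `199.65 − 8.77·1[ACTN3 XX] − 11.68·1[CNTFR CC] + N(0, 27)`.
  The two shifts are the published genotype-contrast differences
  (193.32 − 184.55 and 197.0 − 185.32); the baseline solves the mixture
  equations at the all-weightlifter genotype frequencies so that all four
  published group means are matched in expectation, and the residual sd 27
  approximates the published group sds (24–30). Effects combine additively
  (nothing in the source suggests an interaction).

What the generator does **not** emulate: linkage disequilibrium between
panel loci (the analysis itself never models LD), sex-specific allele
frequencies (the one sex-linked candidate was excluded from the panel for
exactly that reason), and the true within-person correlation of the WRM
loci in the real cohort. Tests that pass on synthetic data therefore
validate the statistical machinery and its calibration, not the biological
claims.

Reproducibility: a config (group sizes, frequency source, effect model) plus
one integer seed determines the cohort byte-for-byte; genotype draws proceed
group by group, locus by locus in panel order, and the performance noise
uses a successor seed, so extending the panel or switching effects off does
not reshuffle unrelated draws.

## Numerical choices and problem sizes

* p-values print at 3 decimals and TGS at 2 in reports, matching the
  precision of the source tables; JSON outputs keep full precision.
* The convolution pmf is validated at total variation < 0.005 against 10⁶
  Monte Carlo draws; type-I error of the t, trend and omnibus tests is
  calibrated at 5000 null replicates of 3 × 20 observations (band
  0.05 ± 0.01); the performance calibration averages 200 simulated cohorts
  of 192 athletes and requires the four genotype-group means within 1 Wilks
  point. These sizes make the full suite complete in under two minutes on a
  single core while keeping Monte Carlo error well inside the asserted
  tolerances.
* The fixture pipeline (`run_study1()`) is deterministic and completes in
  well under a second.

## Known limitations

Count-based routes cannot recover standard deviations or individual-level
p-values (the published 0.04, 0.004, 0.167, 0.02 values); these are
replaced by calibrated-property checks on synthetic cohorts. The published
association grid itself contains several cells that do not recompute from
its own counts under any collapsing convention (e.g. one recessive cell
printing 0.062 where the counts give 0.62); the package asserts the
highlighted, well-determined cells and documents the rest as transcription
noise rather than chasing them. Score models are unweighted (0/1/2 per
locus); effect-size-weighted polygenic scores are out of scope.
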