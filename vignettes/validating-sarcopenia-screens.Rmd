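---
title: "Validating sarcopenia screening instruments: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating sarcopenia screening instruments: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sarcscreen)
```

## The estimation problem

A screening instrument for sarcopenia is judged against a reference
standard: here the AWGS2019 case definition, under which a person is
sarcopenic when muscle mass is low (ASMI below 7.0 kg/m² in males, 5.7 in
females) *and* either muscle strength is low (grip below 28 kg / 18 kg) or
physical performance is low (gait speed below 1.0 m/s). The instrument
under study is the Ishii score chart, a sex-specific linear score over
age, grip strength and calf circumference, dichotomised at a cut-off.
Validation proceeds stratified by sex: classify every participant with
the reference rule, compute the score, estimate the empirical ROC curve
and its AUC with a 95% interval, report the 2×2 accuracy metrics at the
instrument's original cut-off, and select a new cut-off maximising the
Youden index.

## Conventions and their rationale

**Strict `<` at every reference threshold.** The AWGS2019 grip and gait
criteria are stated as strict inequalities; the ASMI criterion is stated
without an operator. We apply strict less-than uniformly, so a value
exactly at a cut is normal. This is a convention, flagged here because
other implementations may include the boundary; it matters only for
measurements landing exactly on a cut, which has probability zero under
continuous measurement.

**Screen positivity is `score >= cutoff` by default.** The original chart
is stated with "≥" cut-offs (105/120), but "more than x points" phrasings
also circulate for re-derived cut-offs, so a `gt` convention is exposed as
an option and every report records which was used. Scores are kept at
full floating precision when compared to cut-offs; display rounding is
two decimal places. Whether published studies rounded scores before
thresholding is generally unstated — full precision is the assumption
least likely to move a boundary case silently.

**Rounding is half-up on the percent scale.** Published accuracy tables
round ties away from zero (the SPSS convention), not to even as base R's
`round()` does; `round_half_up()` implements this and is used for every
displayed percentage. Mixed display precision mirrors the published
tables: sensitivity/specificity and likelihood ratios to 2 decimals,
predictive values to integer percent.

**Predictive values use the study's own prevalence.** PPV and NPV are
proportions among test-positives/-negatives of the observed 2×2 table; no
external prevalence is injected via Bayes' formula. This matches how
validation studies define them and makes every reported metric
recomputable from the archived contingency table.

**Undefined ratios are flagged, never zeroed.** LR+ with perfect
specificity is reported as infinite; 0/0 cases as NaN ("NA" in displays);
a margin with no reference-positive (or -negative) subjects is an error
naming the undefined metric, because no accuracy claim is meaningful
there.

## ROC analysis

Candidate thresholds are the distinct observed scores plus a `+Inf`
sentinel, so the curve starts at (0,0) and ends at (1,1); positivity is
`score >= t`. The AUC is computed by the trapezoidal rule, which on the
empirical curve equals the Mann–Whitney statistic (ties counted one half)
exactly; the package carries both implementations and the test suite
asserts their equivalence on randomised instances, against a brute-force
pairwise oracle, and against the closed-form binormal limit
Φ((μ₁−μ₀)/√(σ₀²+σ₁²)).

The default AUC interval is DeLong's asymptotic method (placement-value
variance, normal interval truncated to [0,1]): it is deterministic, the
standard choice when a published interval's method is unstated, and in
our tests agrees with the independent pROC implementation to full
precision. A stratified-bootstrap percentile interval (default 2000
resamples, seeded) is provided for cross-checking; on moderate samples
the two agree within about 0.02.

**Youden-optimal cut-off.** J = Se + Sp − 1 is evaluated at every
candidate threshold; ties are broken towards the smallest threshold
(maximising sensitivity) and reported. The default candidate grid is the
observed score values; an integer grid is available because published
"new" cut-offs are often integers, suggesting some studies search only
integer points. Selecting a cut-off on the same data that evaluates it is
optimistically biased — the package reproduces the procedure, it does not
endorse it as an unbiased estimate.

## Reconstructing contingency tables from published metrics

Published tables report rounded percentages, but with the margin sizes
known (n reference-positive, n reference-negative) the underlying integer
table is often recoverable: `reconstruct_counts()` enumerates every
(tp, tn) pair whose percentages round (half-up, at the printed precision)
to the published values. Because sensitivity depends only on tp and
specificity only on tn, the exhaustive search factorises and is
instantaneous. Three outcomes are possible and all are surfaced: a unique
table (the useful case — derived PPV/NPV then verify the published row),
several tables (ambiguity is reported, never resolved silently), or none.
The empty case is a genuine finding: one published row in this study's
literature admits no consistent integer table over its stated margins,
indicating unreported analysis-set exclusions or a typo, and the package
reports exactly that rather than forcing a fit.

## The synthetic cohort generator

Individual-level data from validation studies are rarely released, so the
generator emulates the population the published baseline table describes:
941 participants (sex drawn with male fraction 462/941), age drawn by the
published per-sex age-band frequencies (<65, 65–69, 70–79, ≥80) and
uniformly within a band over the recruited range 60–92 years, and the
five continuous measurements (height, ASMI, grip, gait speed, CC) drawn
from a Gaussian copula conditioned on the age draw, with the published
per-sex means and SDs as marginals and truncation to physiologic bounds
(rejection sampling; bounds sit several SDs from every mean, so the
induced marginal distortion is far below one standard error at the sample
sizes used).

**The correlation matrix is a package convention.** No inter-measurement
correlations are published. The shipped default places age in a moderate
negative band against strength, speed and mass (−0.20 to −0.35), and
grip/CC in a positive band against ASMI (+0.50, +0.55), then was fixed
once by checking two emergent properties: the AWGS2019 prevalence of a
large generated cohort is calibratable to the published 18.38%, and the
Ishii score's AUC against emergent status falls in [0.75, 0.90] for both
sexes — the envelope of the published per-sex confidence intervals. It is
documented as calibrated, not estimated.

**Status is emergent, never sampled.** Sarcopenia labels are derived by
running the classifier on the generated measurements. Sampling labels
directly would destroy the dependence between the screened variables and
the reference standard that the ROC analysis exists to measure.

**Prevalence calibration** shifts the ASMI, grip and gait-speed means
jointly (in SD units, SDs fixed, shared across sexes) by deterministic
bisection until the emergent prevalence of a 50 000-person cohort is
within tolerance (default 0.005) of the target; shifts are capped at
0.75 SD because larger shifts would no longer emulate the published
marginals. With the shipped matrix the required shift is about −0.14 SD.

**What passing tests do and do not show.** The generator reproduces
published *marginal* structure plus an assumed Gaussian dependence; real
anthropometric data have skewness, heteroscedasticity, measurement error
and cluster structure the copula does not emulate. Green tests therefore
certify the pipeline's arithmetic and its statistical properties under a
realistic synthetic population — not that the package reproduces the
study's data-dependent numbers (its exact AUCs of 0.84/0.81 and new
cut-offs of 102/95 depend on the unreleased data and are deliberately out
of scope).

## Problem sizes and tolerances

Marginal fidelity and correlation recovery are checked at n = 50 000
(within 3 standard errors and ±0.03 respectively); independence under an
identity copula at n = 20 000 (±0.03); the binormal AUC limit at
n = 20 000 (±0.01); DeLong coverage over 500 replicates of n = 150
(binomial 3-SD band around 0.95); AUC-equivalence over 1000 random small
instances; calibrated emergent prevalence within ±0.01 of 18.38% on a
fresh 50 000-person cohort. These sizes make each stochastic check's
sampling noise several times smaller than its tolerance while keeping the
whole suite in the tens of seconds.

## Known limitations

Single-timepoint cohorts only; no imputation (records failing validation
are excluded and logged, mirroring complete-case analysis); no confidence
intervals on sensitivity/specificity/PPV/NPV (the validation literature
this targets reports none); no smoothed ROC, partial AUC, or paired
AUC-comparison tests; the severe-sarcopenia flag is computed but unused.
The Youden cut-off is selected and evaluated on the same cohort, with the
optimism that implies.
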