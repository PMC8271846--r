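---
title: "Quantifying the whole-body-movement effect on wrist-worn arm-use outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the whole-body-movement effect on wrist-worn arm-use outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(armuse)
```

## The measurement model

Three accelerometers are worn for a week at weeks 3, 12 and 26 post-stroke:
one on each wrist (movement counts only) and one on the nonparetic thigh
(movement counts plus a posture label per sample, one of lying, sitting,
standing, walking, cycling, running). All sensors emit counts at 1.6 Hz and
store them in 30 s epochs of 48 samples; this epoch is the atomic unit of
every aggregation in the package.

Daily arm use is quantified twice from the same retained epochs:

* **P&M**: sum of a wrist's counts over *all* retained epochs;
* **sit/stand**: sum over the epochs whose thigh labels are at least 90%
  sitting or standing (inclusive: 44/48 samples pass, 43/48 fail).

Six outcomes follow per day: paretic and nonparetic arm use and the
paretic/nonparetic ratio, under each method. The ratio is a ratio of daily
sums, not a mean of per-epoch ratios, because the outcome is defined on
daily totals. Per subject-week, outcomes are averaged over the valid
measurement days. The sit/stand outcomes are a sum over a subset of the P&M
epochs, so `paretic_ss <= paretic_pm` holds identically — the difference is
exactly the count mass in non-sit/stand epochs, which is the
whole-body-movement effect under the assumption that arm movements during
whole-body movements (chiefly walking arm sway) are non-functional.

### Wear-time and validity rules

All thresholds are inclusive (`>=`), matching their "at least" definitions:

| rule | value |
|---|---|
| waking-hours window | epoch start in `[07:00, 22:00)` local clock time |
| non-wear | a zero-count run of >= 60 min on a sensor |
| valid day | >= 600 min of simultaneous data from all three sensors |
| valid week | >= 2 valid days |

Decisions the rule definitions leave open, and the choices made here:

* Non-wear is detected **per sensor**, and an epoch contributes to
  whole-configuration wear only if *no* sensor is in non-wear there —
  "data of the whole sensor configuration" is read as all three sensors
  simultaneously delivering data.
* Zero runs are sought on the concatenated 1.6 Hz sample sequence, so a run
  may start mid-epoch; a gap in the epoch sequence (after synchronization or
  the waking-hours cut) ends a run. An epoch is excluded if any part of it
  overlaps a non-wear interval (conservative exclusion). Because runs are
  measured in samples, detection is invariant to how the same samples are
  chunked into epochs.
* Runs are confined to the waking window; whether the original rule let runs
  span the 07:00 boundary is unknowable from its statement, and with the
  window applied first the question does not arise.
* Daily sitting+standing and walking durations are computed at sample
  resolution from the thigh labels (sample count / 96 per minute), not by
  epoch majority — durations are continuous quantities and the label stream
  is available per sample.
* A day is a calendar date; the waking window cannot straddle midnight.

### Degenerate inputs

A ratio with a zero denominator is undefined and propagates as `NA` (never 0
or infinity); weekly ratio means exclude undefined days and report the
contributing day count. Bland–Altman needs >= 2 pairs (the SD is undefined
below that) and its percent difference is undefined when the cohort-mean P&M
value is zero. Spearman correlations need >= 3 complete pairs and are
flagged `"undefined"` when either vector is constant. Epoch streams with
partial rows (< 48 count fields present) are discarded at read time with a
warning; structurally malformed files (wrong field count, negative counts,
non-monotone timestamps, labels on a wrist stream) are hard errors.

## Comparison statistics

**Bland–Altman.** For paired per-subject weekly values, `D = mean(pm - ss)`,
`SDdiff` the sample SD (n−1), `LOA = D ± 1.96·SDdiff`. `D` is also expressed
as a percentage of the cohort-mean P&M outcome at that week — the cohort
mean, not per-subject percentages, so that the denominator is stable at low
individual arm-use levels.

**Spearman.** Ties get average ranks. Interpretation bands are applied to
|r|: < 0.25 very weak, 0.25–0.49 weak, 0.50–0.69 moderate, 0.70–0.89 strong,
0.90–1.00 very strong. (The bands are stated in the literature for positive
r; applying them to |r| extends them symmetrically, and the sign is always
reported alongside.) Cross-sectional correlations use weekly mean daily
values per subject, not pooled days; change scores are per-subject deltas
between weeks 3 and 26 over subjects present at both weeks.

**GEE.** `value ~ time * method` is fit by Gaussian GEE with identity link,
exchangeable working correlation and robust (sandwich) standard errors,
clustered on subject; missing subject-weeks are handled naturally by the
estimating equations. Time is categorical with week 3 as reference and the
method reference is sit/stand, so the `method` coefficient is the
whole-body-movement effect at week 3 and the interactions are its growth.
The scale and correlation are moment estimators (`phi` from the mean squared
residual with a p-degree correction; `rho` from the mean pairwise residual
product, denominator `N_pairs - p`); iteration stops when no coefficient
moves by more than 1e-10, and `rho` is clamped to the valid exchangeable
range. The implementation is written against the estimating equations
directly (no GEE package is used); tests verify it against an independent
dense-matrix solver of the same equations and against the exact identity
with OLS on balanced complete data under a saturated factorial design.

**Post-hoc family.** Bonferroni adjustment is applied to the family
consisting of the method contrast within each week plus the pairwise
between-week contrasts within each method — m = 9 with three weeks. The
family size is reported in the output and the summary header, since the
original analysis states Bonferroni without stating its family.

## The synthetic cohort generator

No subject-level data are deposited for this design, so the package
generates cohorts with the statistical structure the analysis assumes, plus
ground truth for recovery tests. None of the generator's distributions claim
fidelity to a real device or cohort — they are the package's own choices,
selected to be realistic in kind (non-negative, right-skewed counts;
bout-structured postures) and to place the qualitative effects where the
analysis can measure them.

Per subject-day, a posture schedule (minutes of lying, sitting, standing,
walking in the 15 h waking window) is drawn from per-week truncated normals;
walking is drawn first and the sedentary postures are rescaled to fill the
window exactly, so budgets always sum to the window length. The schedule is
laid out as alternating posture bouts with exponential lengths (means 30,
12, 5 and 2.5 min for lying, sitting, standing, walking), which produces the
mixed epochs that exercise the 90% rule. Wrist counts are a sum of three
non-negative components:

* **functional bursts** on sitting/standing samples: zero-inflated gamma —
  per-sample probability 0.10 of a burst with gamma magnitude (shape 2,
  mean 3 counts); the paretic magnitude is multiplied by a deficit in
  [0, 1] whose per-week means (0.35, 0.50, 0.60) rise to emulate recovery;
* **arm sway** on walking samples: truncated-Gaussian per-sample counts,
  mean 1.0 (paretic) and 1.25 (nonparetic, larger by design — the
  explanation offered for the ratio outcome's behaviour), SD 0.3;
* **baseline wear noise** everywhere: a count with probability 0.05 per
  sample, exponential mean 0.3 — so genuinely worn periods essentially never
  produce an hour of zeros by chance.

Walking means rise over weeks (30, 60, 85 min/day) and every subject carries
a persistent log-normal walking multiplier (sdlog 0.35), which is what makes
walking time, and hence the method difference, vary *between* subjects and
gives the correlation analyses something to detect. Non-wear gaps (>= 60
min, probability 0.12 per sensor-day) and sub-threshold short gaps
(10–45 min, probability 0.15, which must *not* trigger the rule) are zeroed
into the streams and recorded in the ground truth; subject-weeks go missing
with per-week probabilities 0.09/0.15/0.21 (mirroring the attrition pattern
of a longitudinal stroke cohort), and days are occasionally truncated.
Counts are rounded to 3 decimals so the CSV round-trip is exact.

Reproducibility: one master seed; per-subject/week/day substreams are
derived by counter-based mixing, so enlarging the cohort never reshuffles
the streams of existing subjects, and identical configurations are
byte-identical.

The generator also has a raw-signal mode used only to exercise the
posture-classifier emulation: the thigh device derives labels from sensor
orientation relative to gravity and movement intensity, and
`emulate_posture_classifier()` implements exactly those two ingredients on
12.5 Hz tri-axial input (inclination of the longitudinal axis, 45°
upright/horizontal threshold; within-window SD of the acceleration magnitude
against walking/running/cycling thresholds of 0.08/0.8/0.3 g; a horizontal
thigh with the anterior surface up is sitting, otherwise lying — a stated
tie-break, since orientation alone cannot separate the two). The thresholds
are configurable defaults, not device constants.

### What the generator does not emulate

No biomechanical gait model, no raw-signal fidelity to any commercial count
algorithm (which is proprietary), no cycling/running/wheelchair dynamics, no
posture-misclassification noise, no diurnal structure within the day beyond
bouts. Passing tests on this cohort therefore demonstrate that the
*pipeline* implements its rules and statistics correctly and that the
analysis recovers effects of the assumed structure — not that any particular
real cohort would show effects of this size.

## Problem sizes

The packaged demonstration cohort (`fixture_config()`) uses 12 subjects ×
3 weeks × 3 days; the full defaults (`sim_config()`) encode the study design
itself (33 subjects, 7 days). Recovery checks use a 20-subject dropout-free
cohort, conservation checks a 10-subject cohort, and the GEE power check 100
replicates of 30 subjects — sizes chosen so the whole suite and the
acceptance script each run in a couple of minutes on one core while keeping
every rule and statistic exercised at realistic scale.

## Known limitations

* The GEE uses the robust sandwich covariance without small-sample
  correction; with very few clusters its Wald tests are liberal.
* Non-wear detection assumes pre-aligned sensor clocks (synchronization
  intersects timestamps; drift is out of scope).
* The posture-classifier emulation is a two-rule idealisation; real devices
  use richer features and temporal smoothing.
* Undefined-ratio handling (exclude and flag) is one defensible choice; the
  original analysis does not state its own.
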