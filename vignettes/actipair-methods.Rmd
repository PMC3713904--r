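---
title: "Validating a phone accelerometer against a research device: methods behind actipair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating a phone accelerometer against a research device: methods behind actipair}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actipair)
```

## The problem

Free-living physical-activity studies increasingly want to replace a
dedicated research accelerometer (worn at the waist, reporting
vertical-axis *counts/min*) with the accelerometer already inside a
participant's phone (reporting gravity-removed vertical acceleration in
*g/min*). Before the phone can stand in for the research device, a
paired-wear validation has to answer three questions: can participants
actually produce usable phone recordings (usability), do the two
instruments rank and scale activity the same way (association and
calibration), and do they agree on the quantities epidemiologists
consume — minutes of light/moderate/vigorous activity and mean intensity
(agreement)? `actipair` implements that whole validation pipeline, plus
a synthetic cohort generator with exact ground truth so that every stage
can be tested without access to any participant data.

## Pipeline and models

The analysis chain for each participant is:

1. **Epoch summarization.** Raw tri-axial samples are reduced to
   1-minute epochs on calendar-minute boundaries, half-open
   `[t, t + 60 s)`. The phone's per-minute value is the mean absolute
   deviation of the vertical axis from its per-minute median. The median
   stands in for the gravity component; this is deliberately
   parameter-free, and a still device yields exactly 0 g/min. Minutes
   with no samples are kept as explicit missing values — downstream
   logic must distinguish "not recorded" from "no movement", so gaps are
   never dropped.
2. **Clock alignment.** Device clocks disagree by up to a few minutes.
   `align()` scans every integer offset in ±5 min (11 candidates),
   computes the adjusted R² of the simple regression between the two
   vertical-axis series over jointly recorded minutes, and merges at the
   argmax. Adjusted R² is `1 − (1 − R²)(n − 1)/(n − 2)`; the small-n
   penalty also makes scores comparable when the overlap n varies
   slightly across candidate offsets, which it does at the series edges.
   Ties break toward the smallest absolute offset, then the negative
   one, so "no shift" wins when the data cannot distinguish. A maximum
   attained at the window edge is flagged, since the true offset may lie
   outside the window. The offset is estimated once per participant over
   all coinciding data, not per day: drift within a few days of wear is
   far below the 1-minute granularity of the search.
3. **Nonwear and usability.** A device is non-worn during any maximal
   run of ≥ 40 consecutive recorded minutes at the device's no-movement
   level — exactly 0 for counts, below 0.3 g for the phone (a level
   free-living night-time phone data sit under). A single minute above
   threshold breaks the run; no interruption tolerance is applied,
   because tolerances interact badly with the phone's noise floor and
   the plain consecutive-minutes rule is transparent. Usability is then
   bookkept per calendar day (midnight-to-midnight on the device's
   clock): days recorded (≥ 1 recorded minute), recorded and worn time,
   percent worn of recorded, valid days (≥ 10 *wearing* hours — a
   config switch selects the recorded-hours variant) and the valid
   assessment flag (≥ 3 valid days). Groups of participants are
   compared metric-by-metric with the tie-corrected Kruskal–Wallis rank
   sum test; when every value ties across groups the test is degenerate
   and is reported as H = 0, p = 1 rather than an error.
4. **Energy expenditure.** Counts are mapped to METs by the Freedson
   linear equation `METs = 1.439008 + 0.000795·VT`. The phone's
   equation, `METs = 1.2907087 + 0.4141791·VT`, is the composition of a
   cross-device unit calibration with the Freedson equation.
   `fit_unit_calibration()` re-derives such a calibration on any
   aligned pair by OLS of counts/min on g/min over jointly worn
   minutes. Because accelerometer noise grows with intensity, the
   reported standard errors are heteroscedasticity-robust (HC1);
   homoscedastic OLS errors understate the slope's sampling variance
   severalfold on realistic data.
5. **Intensity classes.** Minutes are active at ≥ 1.5 METs and
   partitioned at 3 and 6 METs. All class bounds are lower-inclusive
   (`[1.5, 3)`, `[3, 6)`, `[6, ∞)`): the active-time definition fixes
   the inclusive convention at 1.5 and consistency extends it to the
   other cutoffs. A flag switches to the strict `> 1.5` variant.
6. **Agreement battery.** At minute level, comparisons are restricted
   to minutes jointly recorded *and* jointly worn. The pooled
   vertical-axis report carries Spearman correlation (Fisher-z CI,
   variance `1/(n − 3)`) and adjusted R² only — concordance and
   differences across different units are not meaningful. The
   participant-level summaries (active-time %, mean METs, per-class %)
   are compared with Lin's concordance correlation coefficient
   `2·s_xy / (s_x² + s_y² + (x̄ − ȳ)²)` (n-denominator moments; CI by
   Fisher z with Lin's asymptotic variance) and Bland–Altman analysis:
   mean difference, limits `mean ± 1.96·SD`, and a proportional-bias
   regression of differences on pair means `(x + y)/2`, significant
   when the slope's CI excludes zero. Within each intensity class *as
   assigned by the reference device*, the two devices' minute-level
   METs are compared by mean, SD and a two-sided Welch t-test (the
   comparison test is our choice; the means and SDs carry the
   substance). At day level — the sensitivity analysis — only calendar
   days valid on both devices enter, each device contributes its own
   worn minutes without restriction to coinciding periods, and
   per-class min/day are compared with CCC and Bland–Altman. The gap
   between minute-level and day-level agreement measures the influence
   of nonmeasured periods.

### Degenerate inputs and numerical choices

* `ccc`, `spearman_with_ci`, `adjusted_r2` and `bland_altman` remove
  incomplete pairs first and raise informative errors below their
  minimum n (3, 4, 3, 3) or under zero variance; inside the cohort-level
  reports those errors are caught and surface as `NA` fields instead of
  aborting a study.
* Perfect agreement (|CCC| or |rho| = 1) collapses the Fisher-z interval
  to a point rather than producing `atanh(1) = Inf`.
* A constant difference vector gives zero-width limits of agreement and
  a zero bias slope with a `[0, 0]` CI — reported, not an error.
* Participants with zero jointly worn minutes are excluded from the
  minute-level battery with a logged reason code; enrolled = analyzed +
  excluded is asserted by the pipeline.

## The synthetic cohort generator

`simulate_cohort()` emulates the paired-wear study design this package
is aimed at: 36 participants × 5 protocol days by default. One latent
per-minute MET trajectory drives both devices: piecewise-constant bouts
(class probabilities 0.70/0.22/0.065/0.015 for
sedentary/light/moderate/vigorous, geometric lengths of mean 15 min,
within-bout gaussian jitter of SD 0.15 MET) over the waking day, an
overnight both-device nonwear block of mean 9 h, phone-only daytime
nonwear and charging gaps, rarer reference-device nonwear, and a phone
clock offset drawn from ±5 min. Device readings invert each device's
MET equation (so the true cross-device unit link is the ratio of the
two MET slopes, ≈ 521 counts per g) and add multiplicative plus
additive gaussian noise — 3% + 0.01 g for the phone, 5% + 3 counts for
the reference. The additive scales are deliberately small relative to
the sedentary signal: a larger count noise floor clips a substantial
share of worn minutes to exactly zero counts, which silently breaks the
affine unit link the generator itself declares as ground truth and
makes slope recovery impossible. With the defaults, realized wear is
roughly 50–55% of recorded time for the phone and ~60% for the
reference device, matching the compliance levels such deployments
report.

Two scenario knobs exist purely to exercise analyses: an extra
multiplicative phone-noise scale applied only at ≥ 6 METs
(heteroscedastic vigorous error, surfacing as class-specific
proportional bias), and `gap_placement = "sedentary"` (phone recording
gaps during still periods, inflating day-level but not minute-level
differences).

What the generator does **not** emulate: realistic raw waveforms (the
raw synthesizer emits amplitude-compensated 1 Hz sinusoids, good enough
to test epoching, not biomechanics), the manufacturer's band-pass
"count" filter, posture, sleep structure, clock drift within a wearing
period, or seasonal/behavioural day-to-day structure. Passing tests
therefore demonstrate correctness of the statistical machinery under a
controlled data-generating process, not field performance of any
particular phone.

All randomness flows from one seed; a fixed seed makes the cohort
bit-reproducible, and `write_cohort()` stamps the seed into the emitted
manifest and ground-truth files.

### Raw-stream synthesis and the discrete sinusoid factor

For a target epoch value `g`, the raw synthesizer emits
`1 + A·sin(2πt)` at `R` samples/s with `A = g/m`, where
`m = Σ|sin(2πk/R)|/R` is the *discrete-grid* mean of the rectified
sinusoid (`(2/R)·cot(π/R)` for even `R`). Compensating with the grid
mean rather than the continuous `2/π` keeps the epoching round trip
exact to floating-point precision; at 10–30 Hz the two differ by a few
parts in a thousand, which would otherwise eat the round-trip budget.

## Problem sizes in the shipped tests

The test-suite cohorts are deliberately small — typically 1–14
participants over 2–5 days — which is ample because every assertion is
against the generator's exact bookkeeping or an independent arithmetic
oracle, not against asymptotics. The stochastic-property checks use
n = 500–10 000 draws (bias-regression detection, limits-of-agreement
coverage, null Spearman) and 100 seeded cohorts for offset recovery;
these sizes put Monte-Carlo error well below the asserted tolerances.

## Known limitations

* The phone epoch summarization (median-based gravity removal) is a
  declared convention, not a reconstruction of any particular phone
  app's pipeline; absolute g/min values from other pipelines need a
  fresh unit calibration (`fit_unit_calibration()` provides it).
* The alignment search is whole-minute; sub-minute offsets alias into
  neighbouring minutes and slightly attenuate association rather than
  being recovered.
* Calendar days are midnight-to-midnight on each device's own clock; a
  cross-midnight clock offset can split a day's minutes across two
  calendar days, which is visible as an extra "recorded day" in the
  usability table.
* Pooled minute-level correlations treat all participants' minutes as
  exchangeable; the per-participant summaries feeding the CCC are the
  defensible unit of inference for agreement claims.
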