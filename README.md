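# actipair

Paired-device validation of physical-activity measurement: can a phone's
accelerometer stand in for a waist-worn research accelerometer?
`actipair` implements the full validation pipeline for studies in which
participants wear both devices for several free-living days — for
epidemiologists and exercise scientists running (or re-analyzing) such
method-comparison studies.

The pipeline, per participant:

* **Epochs** — raw tri-axial streams are summarized to 1-minute
  vertical-axis epochs (`summarize_to_epochs()`); missing minutes stay
  explicitly coded.
* **Alignment** — the two devices' clocks are merged at the integer
  offset in ±5 min maximizing adjusted R² between the vertical-axis
  series (`align()`).
* **Wear & usability** — nonwear is any run of ≥ 40 consecutive minutes
  at 0 counts/min (reference) or < 0.3 g/min (phone)
  (`detect_nonwear()`); per-day bookkeeping yields valid days (≥ 10
  wearing hours) and valid assessments (≥ 3 valid days)
  (`usability_summary()`), compared across devices by Kruskal–Wallis
  (`compare_usability()`).
* **Energy** — counts map to METs by the Freedson equation
  `METs = 1.439008 + 0.000795·VT`; the phone uses the adapted equation
  `METs = 1.2907087 + 0.4141791·VT` obtained by composing a fitted
  counts-on-g calibration with the Freedson equation
  (`predict_mets()`, `fit_unit_calibration()`). Minutes are active at
  ≥ 1.5 METs and classed light/moderate/vigorous at the 3 and 6 MET
  cutoffs (`classify_intensity()`).
* **Agreement** — Spearman correlation and adjusted R² for the pooled
  vertical-axis measures; Lin's concordance correlation coefficient
  `ccc = 2·s_xy / (s_x² + s_y² + (x̄ − ȳ)²)` and Bland–Altman analysis
  (mean difference, limits `±1.96·SD`, proportional-bias regression of
  differences on pair means) for active time, mean intensity and class
  durations, at minute level over coinciding worn minutes
  (`compare_minutes()`) and at day level over coinciding valid days
  (`compare_days()`).

A synthetic cohort generator (`simulate_cohort()`) emulates the whole
study design — one latent MET trajectory per participant driving both
devices, device noise, nonwear, battery gaps, clock offsets — with
exact ground truth, and `run_study()` orchestrates everything from a
file manifest into a report bundle.

## Worked example

```r
library(actipair)

co  <- simulate_cohort(cohort_config(n_participants = 8,
                                     protocol_days = 5, seed = 42))
res <- analyze_cohort(co)
res
#> <study_results> 8 enrolled, 8 analyzed, 0 excluded
#> minute-level VT: <agreement_report> level minute, n = 28456
#>   Spearman rho 0.968 (0.967-0.969), adj R2 0.995

res$minute$reports$active_pct
#> <agreement_report> level minute, n = 8
#>   Spearman rho 0.976 (0.870-0.996), adj R2 0.987
#>   CCC 0.984 (0.937-0.996)
#>   mean difference -0.2712 (-0.4633--0.0790), LoA -0.7217-0.1793
#>   bias slope -0.0282 (-0.1350-0.0787)

res$offsets                       # estimated phone clock offsets (min)
#> P01 P02 P03 P04 P05 P06 P07 P08
#>  -5   2   0  -4  -3  -2   5   0
sapply(co$truth, `[[`, "offset")  # generator's true offsets
#> P01 P02 P03 P04 P05 P06 P07 P08
#>  -5   2   0  -4  -3  -2   5   0
```

Reading the output: the pooled vertical-axis series of the two devices
correlate strongly over the 28 456 jointly worn minutes (rho 0.968,
adjusted R² 0.995). Per participant, the share of time spent active
(≥ 1.5 METs) agrees almost perfectly between devices (CCC 0.984); the
phone reads on average 0.27 percentage points lower, with no
significant proportional bias (the slope CI spans 0). Every injected
clock offset was recovered exactly.

Re-deriving the phone MET equation from one participant's aligned pair
reproduces the adaptation route:

```r
fit_unit_calibration(res$participant_results[[1]]$pair)
#> <unit_calibration> counts/min = -176.2 + 515.5 * g/min (n = 2939, R2 = 0.994)
#>   composed phone MET equation: <met_model> METs = 1.298957 + 0.4098548 * VT g/min  [fitted]
```

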