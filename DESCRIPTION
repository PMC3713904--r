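Package: actipair
Title: Paired-Device Physical Activity Validation for Accelerometer and
    Smartphone Epoch Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for validating one wearable motion sensor against
    another on free-living data: per-minute epoch summarization of raw
    tri-axial acceleration, integer-minute clock alignment by adjusted
    R-squared search, nonwear detection from sustained near-zero runs,
    wear-time usability accounting, MET estimation through Freedson-style
    linear equations with cross-device unit calibration, intensity
    partitioning at the conventional 1.5/3/6 MET cutoffs, and a full
    agreement battery (Spearman correlation, Lin's concordance correlation
    coefficient, Bland-Altman limits of agreement with proportional-bias
    regression) at minute and day level. Includes a synthetic paired-cohort
    generator with known ground truth and an end-to-end study pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    sandwich,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
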