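Package: sleepreg
Title: Sleep Regularity Index Pipelines for Minute-Epoch Actigraphy Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes the Sleep Regularity Index (SRI) from minute-epoch
    wrist actigraphy: activity-count sleep/wake scoring with a weighted
    five-epoch kernel, eligibility and missing-data filtering, total and
    weekly SRI windows with week-over-week deltas, and the cohort-level
    statistical battery used in inpatient sleep studies (baseline-quartile
    trajectories via repeated-measures ANOVA, mood-disorder group contrasts,
    and Pearson correlations of change scores). Includes a synthetic
    actigraphy cohort generator with named scenarios so every stage of the
    pipeline is testable without access to raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
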