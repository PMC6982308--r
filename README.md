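# sleepreg

Sleep-regularity analysis for minute-epoch wrist actigraphy, built for
longitudinal inpatient cohorts (the motivating setting is a ~3-week
inpatient alcohol-treatment stay, where sleep timing, napping, and mood
comorbidity all move at once). The package takes raw activity-count
recordings from epoch CSVs to cohort-level statistics, with a synthetic
cohort generator so the full pipeline is testable without access to any
participant data.

## What it computes

The core quantity is the **Sleep Regularity Index (SRI)**. Over all epoch
pairs 24 h apart in which both epochs have a valid sleep/wake state, let
*A* be the fraction of pairs whose states agree; then

    SRI = 200 * A - 100

so an identical pattern every day scores 100 and a daily-inverting pattern
scores -100. Around it the package provides:

* **Scoring** (`score_states`): activity counts to sleep/wake states with
  the weighted five-epoch kernel (weights 1/25, 1/5, 1, 1/5, 1/25;
  wake threshold 40), edge- and gap-aware; nap detection by daytime clock
  window (`detect_bouts`, `weekly_nap_minutes`).
* **SRI windows** (`compute_sri`, `weekly_sris`): total and weekly (days
  1-7, 8-14, 15-21) SRIs with day-pair-average or pooled weighting, plus
  week-over-week delta SRIs.
* **Filtering** (`eligibility_filter`, `missingness_report`): the study
  rules — at least 7 recorded days, no day with >= 4 h excluded data in the
  first 21 days — with dropped-participant reasons and a 2/4/6-h
  sensitivity report.
* **Cohort statistics** (`quartile_stratify`, `rm_anova_week`,
  `pearson_test`, `group_compare_total_sri`, `delta_group_ttest`,
  `delta_correlations`): baseline-quartile trajectories via
  repeated-measures ANOVA, mood-disorder contrasts on total SRI, and
  Pearson correlations of change scores.
* **Synthetic cohorts** (`generate_cohort`, `scenario_library`):
  seeded, bytewise-reproducible actigraphy cohorts with bedtime-jitter
  regularity control, naps, off-wrist missingness, a mood subgroup, and
  configurable couplings; scenarios serialize to YAML.

## Worked example

The `analysis/` scripts run a complete study emulation: simulate a
124-participant, 24-day cohort (with regularity improvement concentrated in
irregular sleepers, a mood-disorder gap, and off-wrist missingness), score
and filter it, and run the statistical battery.

```sh
Rscript analysis/01_simulate.R          # writes results/cohort/
Rscript analysis/02_compute_sri.R       # scoring, filtering, SRI windows
Rscript analysis/03_cohort_statistics.R # quartiles, contrasts, correlations
```

With the default seed this prints, in step 02:

```
117 eligible; dropped:
  P001 [MIN_DAYS] 5 recorded days < 7
  P002 [MIN_DAYS] 6 recorded days < 7
  P004 [EXCLUDED_HOURS] 6.00 h excluded on day 4
  ...
  threshold_hours n_participants
1               2            103
2               4              5
3               6              5
Total SRI: mean 73.77, SD 5.98
```

that is, 7 of 124 participants fail the eligibility rules (too-short
recordings or a day with >= 4 excluded hours), 103 have at least one day
with >= 2 h missing, and the eligible cohort's total SRI sits in the
mid-70s. Step 03 then reports (abridged):

```
analysis                       statistic   estimate   p_value    n
rm_anova_bottom_quartile       F_RM_ANOVA    30.87    9.2e-10   29
rm_anova_top_quartile          F_RM_ANOVA     7.18    1.7e-03   29
mood_total_sri_anova           F_ONEWAY      10.29    1.7e-03  117
delta_cor_nap_minutes          PEARSON_R     -0.60    1.8e-12  116
delta_cor_physical_exhaustion  PEARSON_R     -0.20    3.0e-02  116
```

Reading: the least-regular quartile at baseline improves strongly across the
three weeks (F = 30.9); participants with a mood disorder have lower total
SRI (p = 0.0017); and week3-week1 SRI change correlates negatively with the
change in weekly nap minutes (r = -0.60) and in physical exhaustion
(r = -0.20) — sleepers who became more regular napped less and reported
less exhaustion. The top-quartile trajectory also reaches significance here;
the methods vignette (`vignettes/sleep-regularity-methods.Rmd`) explains why
quartile selection on a noisy baseline produces that regression-to-the-mean
pattern and how the dedicated `quartile_improvement` scenario controls it.

`analysis/04_scenario_checks.R` replicates the packaged scenarios across
seeds and tabulates the recovered effects.

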