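---
title: "Sleep regularity from actigraphy: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sleep regularity from actigraphy: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepreg)
```

## The Sleep Regularity Index

The Sleep Regularity Index (SRI) asks a simple question of a sleep/wake
record: if you are asleep at 14:30 today, how likely are you to be asleep at
14:30 tomorrow? Formally, over all pairs of epochs 24 h apart in which both
epochs carry a valid sleep or wake state, let $A$ be the fraction of pairs
whose states agree. Then

$$\mathrm{SRI} = 200\,A - 100.$$

A sleeper whose pattern repeats identically every day scores 100. A pattern
that inverts daily (asleep whenever yesterday awake) scores $-100$; in
practice human data sit far from that floor, and values near the mid-70s with
SDs of 8--10 are typical of inpatient cohorts. Unlike mid-sleep-point
variability, the SRI needs no notion of a "main sleep period", so it handles
napping, fragmented sleep, and irregular schedules gracefully -- which is
exactly why it suits populations in alcohol treatment, where all three are
common.

Note the formula's range is $[-100, 100]$ even though the index is usually
described as 0-to-100; this package implements the formula and does not
clamp, so a pathological anti-periodic input is reported as negative rather
than truncated.

### Windows, day pairs, and averaging

Recordings start mid-day (enrollment day), so a *recording day* is each
successive 24-h block from the first epoch -- days are never snapped to
midnight. Day pair $(d, d+1)$ contributes its per-pair agreement fraction to
a window if its **first** day lies in the window: `TOTAL` uses all days,
`WEEKk` uses days $7(k-1)+1, \dots, 7k$. Two averaging modes are provided:

* `daily_average` (default): the mean of per-day-pair agreement fractions,
  each contributing day pair weighted equally regardless of how many valid
  epoch pairs it has;
* `pooled`: every valid epoch pair weighted equally.

The two are provably identical when no epoch is excluded and all days are
complete (each day then contributes exactly $P = 1440$ pairs), and the test
suite asserts that equality. With missing data they differ slightly;
`daily_average` matches the reading of "averaging all SRIs in the time
interval", and the pooled variant is kept behind a flag because the original
computation cannot be reconstructed more precisely than that.

Pairs in which either epoch is `EXCLUDED` are skipped -- they neither agree
nor disagree. A day pair with no valid pairs is dropped from the average;
a window with no usable day pairs yields `NA`, and `NA`s propagate listwise
into every downstream statistic (no imputation anywhere).

## Sleep/wake scoring

Activity counts are converted to states with the classic weighted
five-epoch kernel: epoch $t$ is scored wake when

$$W_t = \tfrac{1}{25}a_{t-2} + \tfrac{1}{5}a_{t-1} + a_t +
        \tfrac{1}{5}a_{t+1} + \tfrac{1}{25}a_{t+2} \ge 40,$$

the "medium" threshold. The vendor algorithm behind commercial actigraphy
software is proprietary; this scorer is the published form of it, and every
parameter (weights, threshold) is a `scoring_policy()` knob. Where the
kernel window overhangs the recording edge or touches excluded epochs, the
available weights are rescaled to the full kernel mass, otherwise epochs
neighbouring gaps would be biased toward sleep. Scoring is monotone: raising
any activity count can only move epochs toward wake (a property test).

Naps are operationalized from scored states: a maximal sleep run whose first
epoch falls in the 08:00--20:00 clock window and lasting at least 10 min.
The source study derived nap durations "from actigraphy" without stating a
rule, so window and minimum length are policy knobs, defaulted to the
broadest defensible daytime window. Excluded epochs break sleep runs: an
unknown state is never asserted asleep.

## Eligibility filtering

Two ordered checks mirror the study's exclusion narrative: participants with
fewer than 7 recorded days are dropped first (`MIN_DAYS`; a day counts as
recorded if it has at least one non-excluded epoch), then anyone with 4 or
more excluded hours on any single day within the first 21 days
(`EXCLUDED_HOURS`). Both thresholds and the horizon are `filter_policy()`
fields. The `missingness_report()` companion counts participants at
thresholds of 2/4/6 h so the sensitivity of the 4-h choice is visible; the
counts are monotone non-increasing in the threshold by construction.

## The statistical battery

All inferential steps are standard and go through base R's implementations
(`t.test`, `cor.test`, `anova(lm(...))`), except the one-within-factor
repeated-measures ANOVA, which is computed from the balanced-design sums of
squares directly (subject, week, residual; $F = MS_{week}/MS_{resid}$ with
$(w-1, (w-1)(n-1))$ df). The direct computation keeps the df bookkeeping
explicit; the suite cross-checks it against `aov()` with an `Error()`
stratum to $10^{-9}$ and against a hand-computed 4-subject table.
No sphericity correction is applied by default, matching common practice
for a 3-level factor; a Greenhouse--Geisser switch exists. Quartile groups
take the bottom/top $\lfloor n/4 \rfloor$ of week-1 SRI among complete
cases (both group sizes are 24 when $n = 99$), with participant id as a
deterministic tie-break. Two-sample contrasts use pooled variance by default
(Welch optional), and the two-group one-way ANOVA satisfies $F = t^2$
exactly. No multiple-testing correction is applied by default, matching the
exploratory framing; a Benjamini--Hochberg switch is available for the
correlation table.

Change scores are week3 $-$ week1 throughout, for the SRI and for every
clinical covariate. With this orientation the exhaustion coupling is
negative (exhaustion falls as regularity improves); reports that orient the
exhaustion change as a *decrease* will show the same magnitude with positive
sign.

## The synthetic cohort generator

No raw actigraphy from the study is publicly deposited, so the package ships
a generator whose defaults emulate the study conditions: ~124 participants,
21--31 days of 1-min epochs, bedtime-jitter-controlled regularity, daytime
naps, off-wrist missingness blocks, a mood-disorder subgroup with lower
regularity, and week-over-week improvement concentrated in the least regular
quartile.

Per participant and day, bedtime is a clock-time mean plus
$N(0, \sigma_w)$ jitter, where the jitter SD $\sigma_w$ can decay
geometrically toward a floor week over week (the regularization mechanism);
sleep length is normal, truncated to [240, 720] min; within-sleep epochs
become brief awakenings with a fragmentation probability; naps arrive
Poisson per day, uniformly in the daytime window; off-wrist blocks of fixed
length are inserted per day with a given probability. Activity counts are
then drawn conditional on state: sleeping minutes are 80% zeros with small
residual counts, waking minutes are heavy-tailed gamma counts far above the
wake threshold with an 8% sprinkling of sedentary low-count minutes, and
brief awakenings carry moderate counts. These distributions were chosen so
the default scorer recovers truth states with $\ge 95\%$ accuracy on clean
data (in practice ~99%) -- the generator is calibrated to the scorer, not
vice versa. Every participant has a private RNG stream keyed by
`(scenario seed, participant index)`, so cohorts are bytewise reproducible
and insensitive to generation order; the global RNG state is left untouched.

Cohort-level defaults are set to the study's printed orders of magnitude:
mean total SRI in the mid-70s with SD 8--10 and weekly nap totals around
200--215 min. The packaged scenarios encode one pattern each
(`regular_baseline`, `filtering_demo`, `quartile_improvement`, `mood_gap`,
`nap_coupling`, `exhaustion_coupling`, `null_everything`); all serialize to
YAML and back bit-exactly.

### Calibration choices worth knowing about

**Mood gap.** The study reports only the observed significance of the
mood-disorder contrast (p = 0.0157 at N = 120), not a true effect size. The
`mood_gap` scenario multiplies the mood group's bedtime jitter by 1.34,
giving a ~4.3-point true gap -- the smallest effect that a 70/50 split
detects with ~85% power -- rather than a smaller gap that would make the
scenario's defining property (reliable detectability) fail by construction.

**Quartile improvement and regression to the mean.** Weekly SRI estimates
carry measurement noise that grows with bedtime jitter, and selecting the
top quartile on week-1 SRI inflates its week-1 values by selection; with
jitter as the only between-participant axis, the top quartile then shows a
spurious 1--2.5 point decline (the study's own top quartile was borderline,
p = 0.0539 -- plausibly the same artifact). The scenario therefore (a) draws
jitter from a shifted lognormal (12 + lognormal), so the improving bottom
tail is long while the top edge is tight, and (b) adds a second, stable
regularity axis -- a per-participant fragmentation probability uniform on
[0.01, 0.18] -- whose week-to-week noise is near zero because it averages
over thousands of sleep epochs. Top-quartile ranking is then dominated by
true differences and its trajectory is flat.

**Couplings.** The nap coupling is mechanistic: a latent standard-normal
"recovery" score per participant simultaneously shrinks bedtime jitter and
the nap rate week over week, and since naps themselves lower the SRI, the
week3$-$week1 nap change and SRI change are negatively correlated
(calibrated to $\approx -0.6$ at n = 46, the magnitude of the study's
nap correlation). The exhaustion coupling is imposed at covariate-generation
time: the exhaustion change is a linear function of the truth-state SRI
change plus noise, scaled to a target correlation of magnitude 0.24.

**What the generator does not emulate.** Light exposure, circadian phase
(no two-process physiology), medication effects, weekend structure,
seasonality, device-specific count artifacts, or daylight-saving
transitions (timestamps are timezone-naive local clock time). Passing tests
on synthetic cohorts therefore demonstrate that the pipeline recovers the
statistical structure the generator encodes -- not distributional fidelity
to the unavailable raw recordings.

## Numerical and testing choices

Problem sizes were chosen to keep the full suite to roughly a quarter hour
on one CPU while leaving Monte-Carlo error well below the asserted margins:
type-I calibration uses 10,000 summary-level null replicates (binomial SE
~0.2% at $\alpha = 0.05$, against an accepted band of 3--7%); effect
recovery uses 200 epoch-level seeds for the quartile and nap scenarios and
100 for the mood contrast; the generator-vs-scorer loop uses 50
participants. Type-I replication draws participant summaries directly from
the null (`simulate_null_summaries()`) rather than simulating 10,000 full
epoch-level cohorts: the tests under calibration consume only summary
tables, so the summary-level null exercises them identically. The
epoch-level `null_everything` scenario remains available for end-to-end null
runs. Effect-recovery loops feed the generator's truth states to the
pipeline rather than re-scoring activity in every replicate; the
scored-activity route is validated separately (state accuracy and
scored-vs-truth SRI correlation), so the shortcut does not weaken the claim.

Degenerate inputs are handled explicitly: an all-excluded series scores with
a warning and no state changes; a window with no valid pairs gives `NA`
rather than an error mid-cohort; quartile stratification refuses n < 8;
zero-variance inputs to correlations and t-tests are errors, not NaNs.

## Known limitations

* The scorer is a documented stand-in for a proprietary algorithm; absolute
  agreement with vendor software output is not claimed, and sleep-onset
  latency / WASO / efficiency are out of scope.
* The nap rule (clock window + minimum duration) is one defensible
  operationalization of an unstated procedure.
* The `actiware_export` reader is a configurable approximation of an export
  layout that varies across software versions.
* SRI measurement noise at 7-day windows is 2--4 points for irregular
  sleepers; quartile-trajectory analyses on real data inherit the
  regression-to-the-mean caveat discussed above.
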