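#' Define a synthetic cohort scenario
#'
#' A scenario bundles everything needed to draw a cohort: size, recording
#' length, the base [participant_profile()], between-participant
#' heterogeneity, the mood-disorder subgroup structure, and cross-variable
#' couplings. Participants are drawn from the scenario with one private RNG
#' stream each, keyed by `(seed, participant index)`, so cohorts are
#' reproducible and order-independent.
#'
#' Heterogeneity: each participant's bedtime-jitter SD is lognormal
#' (`jitter_meanlog`, `jitter_sdlog`), their mean sleep length normal around
#' the profile value, and their nap rate normal-truncated at zero.
#'
#' Couplings act through a standard-normal latent "recovery" score z per
#' participant: `jitter_z_slope` adds `z * slope` minutes/week to the jitter
#' trend (negative slope: high-z participants regularize) and `nap_z_slope`
#' adds `z * slope` naps/day/week to the nap-rate trend, so SRI improvement
#' and nap reduction co-move. `exhaustion_cor` imposes a target correlation
#' between the week3-week1 SRI change and the week3-week1 exhaustion change
#' at covariate-generation time.
#'
#' @param name scenario label.
#' @param n_participants cohort size.
#' @param n_days recording days per participant.
#' @param epoch_seconds epoch length.
#' @param seed integer scenario seed.
#' @param profile base [participant_profile()] (a plain list is accepted).
#' @param heterogeneity list: `jitter_meanlog`, `jitter_sdlog`,
#'   `sleep_duration_between_sd`, `nap_rate_between_sd`, and optionally
#'   `jitter_shift` (additive minimum jitter, giving a shifted-lognormal
#'   spread) and `frag_range` (length-2: per-participant fragmentation
#'   probability drawn uniformly from this range — a stable, person-level
#'   regularity axis).
#' @param mood list: either `prob` (Bernoulli mood flag) or `n_mood` (exact
#'   count, assigned to a random subset), plus `jitter_mult` applied to the
#'   mood group's jitter SD (>1: less regular sleep).
#' @param coupling list: `jitter_z_slope`, `nap_z_slope`, `exhaustion_cor`,
#'   `exhaustion_delta_sd`.
#' @param overrides optional list of per-participant-index override lists;
#'   entries may set any profile field and/or `n_days`.
#' @return an object of class `cohort_scenario`.
#' @export
cohort_scenario <- function(name = "custom",
                            n_participants = 10L,
                            n_days = 21L,
                            epoch_seconds = 60L,
                            seed = 20200103L,
                            profile = participant_profile(),
                            heterogeneity = list(jitter_meanlog = log(40),
                                                 jitter_sdlog = 0.45,
                                                 sleep_duration_between_sd = 35,
                                                 nap_rate_between_sd = 0.3),
                            mood = list(prob = 0.565, jitter_mult = 1),
                            coupling = list(jitter_z_slope = 0,
                                            nap_z_slope = 0,
                                            exhaustion_cor = 0,
                                            exhaustion_delta_sd = 2),
                            overrides = list()) {
  if (n_participants < 1L || n_days < 1L) {
    stop("n_participants and n_days must be >= 1", call. = FALSE)
  }
  structure(
    list(name = name, n_participants = as.integer(n_participants),
         n_days = as.integer(n_days), epoch_seconds = as.integer(epoch_seconds),
         seed = as.integer(seed), profile = unclass(profile),
         heterogeneity = heterogeneity, mood = mood, coupling = coupling,
         overrides = overrides),
    class = "cohort_scenario"
  )
}

#' Serialize / restore a scenario as YAML
#'
#' @param scenario a [cohort_scenario()].
#' @param text YAML string produced by `scenario_to_yaml`.
#' @return `scenario_to_yaml`: a YAML string; `scenario_from_yaml`: the
#'   restored `cohort_scenario`.
#' @export
scenario_to_yaml <- function(scenario) {
  stopifnot(inherits(scenario, "cohort_scenario"))
  # precision 17 makes doubles round-trip bit-exactly
  yaml::as.yaml(unclass(scenario), precision = 17)
}

#' @rdname scenario_to_yaml
#' @export
scenario_from_yaml <- function(text) {
  x <- yaml::yaml.load(text)
  do.call(cohort_scenario, c(
    x[c("name", "n_participants", "n_days", "epoch_seconds", "seed",
        "heterogeneity", "mood", "coupling")],
    list(profile = do.call(participant_profile, x$profile),
         overrides = if (is.null(x$overrides)) list() else x$overrides)
  ))
}

## Private per-participant seed below 2^31.
participant_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 1000003 * i) %% 2147483647)
}

#' Generate a synthetic cohort
#'
#' Draws per-participant latent parameters from the scenario (cohort-level
#' stream), then simulates each participant's epoch series on a private
#' stream. Returns the series, a covariate table (mood/anxiety flags, weekly
#' mental and physical exhaustion, day-28 sleep-quality and withdrawal
#' scores), and a truth table holding every latent parameter plus the
#' truth-state weekly SRIs for recovery tests.
#'
#' @param scenario a [cohort_scenario()].
#' @param n_participants,seed optional overrides of the scenario fields.
#' @param with_activity draw activity counts (see [generate_participant()]).
#' @param compute_truth_sri fill the truth table's SRI columns (forced on
#'   when the scenario couples exhaustion to the SRI change, which needs
#'   them); skipping saves time in large replicate studies that re-derive
#'   SRIs through the pipeline anyway.
#' @return list with `series` (named list of [epoch_series()]),
#'   `covariates`, `truth` (data.frames), and `scenario`.
#' @export
generate_cohort <- function(scenario, n_participants = NULL, seed = NULL,
                            with_activity = TRUE, compute_truth_sri = TRUE) {
  stopifnot(inherits(scenario, "cohort_scenario"))
  n <- if (is.null(n_participants)) scenario$n_participants else
    as.integer(n_participants)
  sd0 <- if (is.null(seed)) scenario$seed else as.integer(seed)
  het <- scenario$heterogeneity
  cpl <- scenario$coupling
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(sd0)

  ids <- sprintf("P%03d", seq_len(n))
  shift <- if (is.null(het$jitter_shift)) 0 else het$jitter_shift
  jitter <- pmin(200, pmax(5, shift + stats::rlnorm(n, het$jitter_meanlog,
                                                    het$jitter_sdlog)))
  sleep_mean <- pmin(700, pmax(260, stats::rnorm(
    n, scenario$profile$sleep_duration_mean, het$sleep_duration_between_sd)))
  nap_rate <- pmax(0, stats::rnorm(n, scenario$profile$nap_rate_per_day,
                                   het$nap_rate_between_sd))
  mood <- if (!is.null(scenario$mood$n_mood)) {
    m <- rep(FALSE, n); m[sample.int(n, min(n, scenario$mood$n_mood))] <- TRUE; m
  } else stats::runif(n) < scenario$mood$prob
  jitter[mood] <- pmin(200, jitter[mood] * scenario$mood$jitter_mult)
  frag <- if (!is.null(het$frag_range)) {
    stats::runif(n, het$frag_range[1], het$frag_range[2])
  } else rep(scenario$profile$wake_fragmentation_prob, n)
  z <- stats::rnorm(n)
  anxiety <- stats::runif(n) < 0.5
  base_mexh <- pmin(9, pmax(1, stats::rnorm(n, 5.5, 1.3)))
  base_pexh <- pmin(9, pmax(1, stats::rnorm(n, 5.5, 1.3)))
  psqi_day28 <- pmax(0, round(stats::rnorm(n, 6.5, 3.8)))
  max_ciwa <- pmax(0, round(stats::rnorm(n, 7.7, 5.6)))
  pseeds <- vapply(seq_len(n), function(i) participant_seed(sd0, i), integer(1))

  series <- vector("list", n)
  names(series) <- ids
  truth_sri <- matrix(NA_real_, n, 4,
                      dimnames = list(NULL, c("TOTAL", "WEEK1", "WEEK2", "WEEK3")))
  jt <- numeric(n); nt <- numeric(n); nd_i <- integer(n)
  for (i in seq_len(n)) {
    jt[i] <- scenario$profile$jitter_trend_per_week + cpl$jitter_z_slope * z[i]
    nt[i] <- scenario$profile$nap_rate_trend_per_week + cpl$nap_z_slope * z[i]
    args <- utils::modifyList(scenario$profile, list(
      bedtime_jitter_sd = jitter[i],
      sleep_duration_mean = sleep_mean[i],
      nap_rate_per_day = nap_rate[i],
      jitter_trend_per_week = jt[i],
      nap_rate_trend_per_week = nt[i],
      wake_fragmentation_prob = frag[i],
      mood_disorder = mood[i]
    ))
    nd <- scenario$n_days
    ov <- if (i <= length(scenario$overrides)) scenario$overrides[[i]] else NULL
    if (!is.null(ov)) {
      if (!is.null(ov$n_days)) { nd <- ov$n_days; ov$n_days <- NULL }
      args <- utils::modifyList(args, ov)
    }
    nd_i[i] <- nd
    prof <- do.call(participant_profile, args)
    series[[i]] <- generate_participant(prof, n_days = nd,
                                        epoch_seconds = scenario$epoch_seconds,
                                        seed = pseeds[i], participant_id = ids[i],
                                        with_activity = with_activity)
    if (compute_truth_sri || cpl$exhaustion_cor != 0) {
      ws <- weekly_sris(series[[i]])
      truth_sri[i, ] <- stats::setNames(ws$weekly$sri, ws$weekly$window)[
        c("TOTAL", "WEEK1", "WEEK2", "WEEK3")]
    }
  }

  dsri <- truth_sri[, "WEEK3"] - truth_sri[, "WEEK1"]
  mexh <- exhaustion_weeks(base_mexh, dsri, cpl$exhaustion_cor,
                           cpl$exhaustion_delta_sd)
  pexh <- exhaustion_weeks(base_pexh, dsri, cpl$exhaustion_cor,
                           cpl$exhaustion_delta_sd)

  covariates <- data.frame(
    participant_id = ids, mood_disorder = mood, anxiety_disorder = anxiety,
    mexh_week1 = mexh[, 1], mexh_week2 = mexh[, 2], mexh_week3 = mexh[, 3],
    pexh_week1 = pexh[, 1], pexh_week2 = pexh[, 2], pexh_week3 = pexh[, 3],
    psqi_day28 = psqi_day28, max_ciwa = max_ciwa,
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    participant_id = ids, seed = pseeds, n_days = nd_i,
    bedtime_jitter_sd = jitter, jitter_trend_per_week = jt,
    sleep_duration_mean = sleep_mean, nap_rate_per_day = nap_rate,
    nap_rate_trend_per_week = nt, wake_fragmentation_prob = frag,
    latent_z = z, mood_disorder = mood,
    sri_total = truth_sri[, "TOTAL"], sri_week1 = truth_sri[, "WEEK1"],
    sri_week2 = truth_sri[, "WEEK2"], sri_week3 = truth_sri[, "WEEK3"],
    stringsAsFactors = FALSE
  )
  list(series = series, covariates = covariates, truth = truth,
       scenario = scenario)
}

## Weekly exhaustion scores whose week3-week1 change correlates with the
## SRI change at the requested level (0 = pure noise).
exhaustion_weeks <- function(base, dsri, target_cor, delta_sd) {
  n <- length(base)
  zs <- rep(0, n)
  ok <- !is.na(dsri)
  if (target_cor != 0 && sum(ok) > 2 && stats::sd(dsri[ok]) > 0) {
    zs[ok] <- (dsri[ok] - mean(dsri[ok])) / stats::sd(dsri[ok])
  }
  delta <- target_cor * delta_sd * zs +
    sqrt(max(0, 1 - target_cor^2)) * delta_sd * stats::rnorm(n)
  w1 <- base
  w3 <- pmin(10, pmax(0, base + delta))
  w2 <- pmin(10, pmax(0, base + delta / 2 + stats::rnorm(n, 0, 0.5)))
  cbind(w1, w2, w3)
}

#' Named scenario library
#'
#' Packaged cohort scenarios mirroring the study's structure:
#'
#' * `regular_baseline` — heterogeneous but stable sleepers at the study's
#'   scale (cohort mean SRI around the mid-70s, SD 8-10); no couplings.
#' * `filtering_demo` — 10 participants: 2 with recordings shorter than 7
#'   days, 3 with a forced off-wrist block of 4+ h on one day, 5 clean.
#' * `quartile_improvement` — wide baseline-regularity spread with jitter
#'   decaying toward a floor, so improvement concentrates in the least
#'   regular quartile.
#' * `mood_gap` — 70 of 120 participants carry a mood disorder and sleep
#'   less regularly (a few SRI points lower on average).
#' * `nap_coupling` — a latent recovery score drives jitter reduction and
#'   nap reduction jointly, giving a negative SRI-change/nap-change
#'   correlation near -0.6.
#' * `exhaustion_coupling` — exhaustion change correlated with SRI change
#'   (magnitude 0.24; exhaustion falls as regularity improves).
#' * `null_everything` — no trends, no couplings; for type-I calibration.
#'
#' @param name scenario name; omit to get the full named list.
#' @return a [cohort_scenario()] or a named list of them.
#' @export
scenario_library <- function(name = NULL) {
  lib <- list(
    regular_baseline = cohort_scenario(
      name = "regular_baseline", n_participants = 124L, n_days = 24L),
    filtering_demo = cohort_scenario(
      name = "filtering_demo", n_participants = 10L, n_days = 21L,
      overrides = list(
        list(n_days = 5L), list(n_days = 6L),
        list(forced_missing_day = 3L, forced_missing_hours = 6.5),
        list(forced_missing_day = 5L, forced_missing_hours = 5),
        list(forced_missing_day = 9L, forced_missing_hours = 4.5),
        list(forced_missing_day = 12L, forced_missing_hours = 2.5)
      )),
    quartile_improvement = cohort_scenario(
      name = "quartile_improvement", n_participants = 99L,
      profile = participant_profile(jitter_floor = 20,
                                    jitter_decay_per_week = 0.45,
                                    nap_rate_per_day = 0.1,
                                    sleep_duration_sd = 6),
      heterogeneity = list(jitter_shift = 12, jitter_meanlog = log(25),
                           jitter_sdlog = 0.8,
                           sleep_duration_between_sd = 35,
                           nap_rate_between_sd = 0.05,
                           frag_range = c(0.01, 0.18))),
    mood_gap = cohort_scenario(
      name = "mood_gap", n_participants = 120L,
      mood = list(n_mood = 70L, jitter_mult = 1.42)),
    nap_coupling = cohort_scenario(
      name = "nap_coupling", n_participants = 46L,
      profile = participant_profile(nap_rate_per_day = 1.0),
      heterogeneity = list(jitter_meanlog = log(45), jitter_sdlog = 0.4,
                           sleep_duration_between_sd = 35,
                           nap_rate_between_sd = 0.2),
      coupling = list(jitter_z_slope = -3, nap_z_slope = -0.18,
                      exhaustion_cor = 0, exhaustion_delta_sd = 2)),
    exhaustion_coupling = cohort_scenario(
      name = "exhaustion_coupling", n_participants = 99L,
      coupling = list(jitter_z_slope = -5, nap_z_slope = 0,
                      exhaustion_cor = -0.24, exhaustion_delta_sd = 2)),
    null_everything = cohort_scenario(
      name = "null_everything", n_participants = 124L,
      mood = list(prob = 0.5, jitter_mult = 1))
  )
  if (is.null(name)) return(lib)
  if (!name %in% names(lib)) {
    stop("unknown scenario: ", name, " (known: ",
         paste(names(lib), collapse = ", "), ")", call. = FALSE)
  }
  lib[[name]]
}

#' Draw participant-summary tables from the global null
#'
#' A summary-level null generator for type-I calibration of the statistical
#' battery: weekly SRIs, nap minutes, and exhaustion scores are mutually
#' independent with no week effect, no group effect, and no coupling, so
#' every test's null hypothesis holds exactly. Operating at the summary
#' level (rather than simulating epochs) is what makes 10,000-replicate
#' calibration runs affordable.
#'
#' @param n participants per table.
#' @param seed RNG seed.
#' @return a cohort summary data.frame in the layout of
#'   [build_cohort_table()].
#' @export
simulate_null_summaries <- function(n = 20L, seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  sri <- matrix(stats::rnorm(3 * n, 76, 8), n, 3)
  nap <- matrix(stats::rgamma(3 * n, shape = 1.2, scale = 180), n, 3)
  mexh <- matrix(pmin(10, pmax(0, stats::rnorm(3 * n, 5.5, 1.5))), n, 3)
  pexh <- matrix(pmin(10, pmax(0, stats::rnorm(3 * n, 5.5, 1.5))), n, 3)
  data.frame(
    participant_id = sprintf("N%04d", seq_len(n)),
    sri_total = rowMeans(sri),
    sri_week1 = sri[, 1], sri_week2 = sri[, 2], sri_week3 = sri[, 3],
    delta_w2_w1 = sri[, 2] - sri[, 1],
    delta_w3_w2 = sri[, 3] - sri[, 2],
    delta_w3_w1 = sri[, 3] - sri[, 1],
    nap_week1 = nap[, 1], nap_week2 = nap[, 2], nap_week3 = nap[, 3],
    delta_nap_w3_w1 = nap[, 3] - nap[, 1],
    delta_mexh_w3_w1 = mexh[, 3] - mexh[, 1],
    delta_pexh_w3_w1 = pexh[, 3] - pexh[, 1],
    mood_disorder = stats::runif(n) < 0.5,
    stringsAsFactors = FALSE
  )
}
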