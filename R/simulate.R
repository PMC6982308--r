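#' Synthetic participant profile
#'
#' Latent parameters of one simulated sleeper. Each night's bedtime is the
#' profile mean plus Gaussian jitter; the jitter SD can shrink week over week
#' (geometric decay toward a floor, plus an additive linear trend, negative =
#' regularizing), which is how regularity improvement during an inpatient
#' stay is emulated. Sleep length is truncated-normal in [240, 720] minutes.
#' Daytime naps arrive Poisson per day inside the nap clock window; the nap
#' rate can also trend across weeks. Brief within-sleep awakenings occur per
#' epoch with a fragmentation probability. Off-wrist missingness is inserted
#' as whole blocks.
#'
#' @param bedtime_mean clock time `"HH:MM"`.
#' @param bedtime_jitter_sd SD of nightly bedtime jitter, minutes.
#' @param jitter_floor,jitter_decay_per_week,jitter_trend_per_week weekly
#'   evolution of the jitter SD: the excess above the floor decays
#'   geometrically, `sd_w = min(sd, floor) + max(0, sd - floor) *
#'   decay^(w-1) + trend * (w-1)`, truncated at 0; sleepers already at or
#'   below the floor are unaffected by the decay.
#' @param sleep_duration_mean,sleep_duration_sd nightly sleep length,
#'   minutes.
#' @param nap_rate_per_day expected naps per day.
#' @param nap_rate_trend_per_week additive change in the nap rate per week.
#' @param nap_duration_mean,nap_duration_sd nap length, minutes.
#' @param wake_fragmentation_prob per-epoch probability a sleep epoch is a
#'   brief awakening.
#' @param mood_disorder logical flag carried into the covariate table.
#' @param missing_block_prob_per_day probability a day contains an off-wrist
#'   block.
#' @param missing_block_hours length of an off-wrist block, hours.
#' @param forced_missing_day,forced_missing_hours optionally force one
#'   off-wrist block of the given length on a specific recording day
#'   (deterministic missingness for filter demonstrations).
#' @return an object of class `participant_profile`.
#' @export
participant_profile <- function(bedtime_mean = "23:30",
                                bedtime_jitter_sd = 45,
                                jitter_floor = 0,
                                jitter_decay_per_week = 1,
                                jitter_trend_per_week = 0,
                                sleep_duration_mean = 430,
                                sleep_duration_sd = 30,
                                nap_rate_per_day = 0.8,
                                nap_rate_trend_per_week = 0,
                                nap_duration_mean = 40,
                                nap_duration_sd = 15,
                                wake_fragmentation_prob = 0.02,
                                mood_disorder = FALSE,
                                missing_block_prob_per_day = 0,
                                missing_block_hours = 2,
                                forced_missing_day = NA_integer_,
                                forced_missing_hours = NA_real_) {
  p <- as.list(environment())
  if (p$bedtime_jitter_sd < 0 || p$sleep_duration_sd < 0 ||
      p$nap_rate_per_day < 0 || p$nap_duration_sd < 0) {
    stop("SDs and rates must be non-negative", call. = FALSE)
  }
  if (p$wake_fragmentation_prob < 0 || p$wake_fragmentation_prob > 1 ||
      p$missing_block_prob_per_day < 0 || p$missing_block_prob_per_day > 1) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (p$sleep_duration_mean < 240 - 4 * max(p$sleep_duration_sd, 1) ||
      p$sleep_duration_mean > 720 + 4 * max(p$sleep_duration_sd, 1)) {
    stop("sleep_duration_mean incompatible with the [240, 720] truncation",
         call. = FALSE)
  }
  structure(p, class = "participant_profile")
}

## Truncated-normal draw by rejection inside [lo, hi].
rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(min(max(mean, lo), hi), n))
  out <- numeric(n)
  for (i in seq_len(n)) {
    for (try in 1:1000) {
      x <- stats::rnorm(1, mean, sd)
      if (x >= lo && x <= hi) break
      if (try == 1000) x <- min(max(mean, lo), hi)
    }
    out[i] <- x
  }
  out
}

#' Generate one synthetic participant's actigraphy record
#'
#' Simulates truth sleep/wake states on a minute grid from the profile, then
#' draws activity counts conditional on state: sleeping minutes are mostly
#' zeros with occasional small counts, waking minutes are heavy-tailed
#' counts far above the scorer's wake threshold (with a sprinkling of
#' sedentary low-count minutes). Off-wrist blocks become EXCLUDED epochs.
#' The recording starts at 12:00 local clock, as inpatient enrollment days
#' do. Identical `(profile, n_days, seed)` give bit-identical output.
#'
#' @param profile a [participant_profile()].
#' @param n_days recording length in days.
#' @param epoch_seconds epoch length (60 is the only length the activity
#'   model is calibrated for).
#' @param seed integer RNG seed for this participant's private stream.
#' @param participant_id id string.
#' @param with_activity draw activity counts (default). With `FALSE` the
#'   activity column is zero/`NA` and only truth states are produced; the
#'   states are bit-identical to the `TRUE` case for the same seed because
#'   activity is drawn last.
#' @return an [epoch_series()] whose `state` column holds the truth states.
#' @export
generate_participant <- function(profile, n_days = 21L, epoch_seconds = 60L,
                                 seed = 1L, participant_id = "sim",
                                 with_activity = TRUE) {
  stopifnot(inherits(profile, "participant_profile"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  P <- 86400L %/% as.integer(epoch_seconds)
  epm <- epoch_seconds / 60          # minutes per epoch
  n <- as.integer(n_days) * P
  start_clock <- 720                  # recording starts at 12:00
  start <- as.POSIXct("2024-01-01 12:00:00", tz = "UTC")

  state <- rep("WAKE", n)

  week_of_day <- function(d) (d - 1L) %/% 7L + 1L
  jitter_sd_for <- function(d) {
    w <- week_of_day(d)
    # the decay shrinks only the excess above the floor, so sleepers already
    # at or below the floor stay where they are
    base <- min(profile$bedtime_jitter_sd, profile$jitter_floor)
    excess <- max(0, profile$bedtime_jitter_sd - profile$jitter_floor)
    max(0, base + excess * profile$jitter_decay_per_week^(w - 1) +
          profile$jitter_trend_per_week * (w - 1))
  }

  bed_clock <- parse_clock(profile$bedtime_mean)
  # absolute minute (0-based from recording start) of each night's bedtime
  for (d in seq_len(n_days)) {
    jit <- stats::rnorm(1, 0, jitter_sd_for(d))
    dur <- rtruncnorm1(1, profile$sleep_duration_mean,
                       profile$sleep_duration_sd, 240, 720)
    bed_abs <- (d - 1) * 1440 + (bed_clock - start_clock) %% 1440 + jit
    i0 <- max(1L, as.integer(floor(bed_abs / epm)) + 1L)
    i1 <- min(n, as.integer(floor((bed_abs + dur) / epm)))
    if (i0 <= i1) state[i0:i1] <- "SLEEP"
  }

  # daytime naps inside the clock window; the window's within-day offsets are
  # identical every day because the grid is clock-anchored
  clock1 <- (start_clock + (seq_len(P) - 1) * epm) %% 1440
  nap_lo <- parse_clock("08:00"); nap_hi <- parse_clock("20:00")
  nap_offsets <- which(clock1 >= nap_lo & clock1 < nap_hi)
  for (d in seq_len(n_days)) {
    rate <- max(0, profile$nap_rate_per_day +
                  profile$nap_rate_trend_per_week * (week_of_day(d) - 1))
    k <- stats::rpois(1, rate)
    if (k == 0) next
    eligible <- (d - 1L) * P + nap_offsets
    for (j in seq_len(k)) {
      st <- sample(eligible, 1)
      len <- max(10, min(180, round(stats::rnorm(1, profile$nap_duration_mean,
                                                 profile$nap_duration_sd))))
      en <- min(n, st + as.integer(len / epm) - 1L)
      state[st:en] <- "SLEEP"
    }
  }

  # brief awakenings fragment the sleep
  sleep_idx <- which(state == "SLEEP")
  if (profile$wake_fragmentation_prob > 0 && length(sleep_idx) > 0) {
    frag <- sleep_idx[stats::runif(length(sleep_idx)) <
                        profile$wake_fragmentation_prob]
    state[frag] <- "WAKE"
  } else {
    frag <- integer(0)
  }

  # off-wrist blocks
  off <- rep(FALSE, n)
  for (d in seq_len(n_days)) {
    hit <- stats::runif(1) < profile$missing_block_prob_per_day
    forced <- !is.na(profile$forced_missing_day) &&
      d == profile$forced_missing_day
    if (!hit && !forced) next
    hours <- if (forced) profile$forced_missing_hours else
      profile$missing_block_hours
    len <- as.integer(round(hours * 3600 / epoch_seconds))
    st <- (d - 1L) * P + sample.int(max(1L, P - len + 1L), 1)
    en <- min(n, st + len - 1L)
    off[st:en] <- TRUE
  }

  # activity counts conditional on truth state
  activity <- numeric(n)
  wake_idx <- if (with_activity) which(state == "WAKE") else integer(0)
  sl_idx <- if (with_activity) which(state == "SLEEP") else integer(0)
  if (!with_activity) frag <- integer(0)
  if (length(sl_idx) > 0) {
    quiet <- stats::runif(length(sl_idx)) < 0.8
    activity[sl_idx] <- ifelse(quiet, 0, stats::rpois(length(sl_idx), 8))
  }
  if (length(wake_idx) > 0) {
    a <- stats::rgamma(length(wake_idx), shape = 1.2, scale = 250)
    sedentary <- stats::runif(length(wake_idx)) < 0.08
    a[sedentary] <- stats::runif(sum(sedentary), 0, 20)
    activity[wake_idx] <- round(a)
  }
  # brief awakenings carry moderate movement, not full daytime activity
  if (length(frag) > 0) {
    activity[frag] <- round(stats::rgamma(length(frag), shape = 2, scale = 60))
  }

  final_state <- state
  final_state[off] <- "EXCLUDED"
  activity[off] <- NA_real_

  epoch_series(participant_id,
               start + (seq_len(n) - 1) * epoch_seconds,
               activity, final_state, off, epoch_seconds = epoch_seconds)
}
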