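#' Eligibility filter policy
#'
#' Thresholds for including a participant in the SRI analysis: at least
#' `min_days` recorded days overall, and no day within the first
#' `horizon_days` days carrying `max_excluded_hours_per_day` or more hours of
#' excluded (off-wrist/invalid) data.
#'
#' @param min_days minimum recorded days (default 7).
#' @param max_excluded_hours_per_day exclusion threshold in hours per day
#'   (default 4; the comparison is `>=`).
#' @param horizon_days how many leading recording days the exclusion check
#'   covers (default 21).
#' @return an object of class `filter_policy`.
#' @export
filter_policy <- function(min_days = 7L,
                          max_excluded_hours_per_day = 4,
                          horizon_days = 21L) {
  if (min_days <= 0 || max_excluded_hours_per_day <= 0 || horizon_days <= 0) {
    stop("all filter_policy fields must be positive", call. = FALSE)
  }
  structure(
    list(min_days = as.integer(min_days),
         max_excluded_hours_per_day = as.numeric(max_excluded_hours_per_day),
         horizon_days = as.integer(horizon_days)),
    class = "filter_policy"
  )
}

## Per-epoch agreement with the epoch 24 h later: +1 match, 0 mismatch,
## NA when either side is EXCLUDED/unscored or beyond the recording.
pair_agreement_vector <- function(series) {
  s <- match(series$epochs$state, EPOCH_STATES)  # 1 WAKE, 2 SLEEP, 3 EXCLUDED
  n <- length(s)
  P <- epochs_per_day(series)
  out <- rep(NA_real_, n)
  if (n <= P) return(out)
  a <- s[seq_len(n - P)]
  b <- s[(P + 1L):n]
  ok <- !is.na(a) & !is.na(b) & a != 3L & b != 3L
  out[seq_len(n - P)][ok] <- as.numeric(a[ok] == b[ok])
  out
}

## SRI over a set of first-days of day pairs, from a precomputed pair vector.
sri_from_pairvec <- function(v, P, days, mode, window) {
  nd <- as.integer(ceiling(length(v) / P))
  pad <- nd * P - length(v)
  m <- matrix(c(v, rep(NA_real_, pad)), nrow = P)  # one column per day
  m <- m[, days[days <= nd], drop = FALSE]
  counts <- colSums(!is.na(m))
  valid_pairs <- sum(counts)
  if (valid_pairs == 0L) {
    return(data.frame(window = window, sri = NA_real_, agreement = NA_real_,
                      valid_pairs = 0L, day_pairs_used = 0L,
                      stringsAsFactors = FALSE))
  }
  sums <- colSums(m, na.rm = TRUE)
  use <- counts > 0L
  agreement <- if (mode == "daily_average") {
    mean(sums[use] / counts[use])
  } else {
    sum(sums) / valid_pairs
  }
  data.frame(window = window, sri = 200 * agreement - 100,
             agreement = agreement, valid_pairs = as.integer(valid_pairs),
             day_pairs_used = as.integer(sum(use)), stringsAsFactors = FALSE)
}

#' Agreement between one recording day and the next
#'
#' For each epoch t of recording day `day` whose state and the state 24 h
#' later are both scored sleep or wake, the pair agrees when the two states
#' match. Returns the fraction of agreeing pairs and the number of valid
#' pairs; agreement is `NA` when no pair is valid (including days beyond the
#' recording).
#'
#' @param series a scored [epoch_series()].
#' @param day positive recording-day index (day pairs are `(day, day + 1)`).
#' @return list with `agreement` (fraction in `[0,1]` or `NA`) and
#'   `valid_pairs` (integer).
#' @export
day_pair_agreement <- function(series, day) {
  stopifnot(day >= 1)
  P <- epochs_per_day(series)
  v <- pair_agreement_vector(series)
  lo <- (day - 1L) * P + 1L
  hi <- min(day * P, length(v))
  if (lo > length(v)) return(list(agreement = NA_real_, valid_pairs = 0L))
  seg <- v[lo:hi]
  k <- sum(!is.na(seg))
  list(agreement = if (k > 0) mean(seg, na.rm = TRUE) else NA_real_,
       valid_pairs = as.integer(k))
}

#' Compute the Sleep Regularity Index over a window
#'
#' The SRI measures the probability of being in the same sleep/wake state at
#' clock times 24 h apart: per-day-pair agreement fractions are averaged over
#' the window and mapped through `200 * agreement - 100`, giving 100 for a
#' perfectly periodic sleeper and -100 for a pattern that inverts daily.
#' Pairs touching an EXCLUDED epoch are skipped; day pairs with no valid
#' pair are dropped from the average.
#'
#' Window membership is by the FIRST day of each `(d, d+1)` pair: `TOTAL`
#' uses all recording days, `WEEKk` uses days `7(k-1)+1 .. 7k`.
#'
#' Two averaging modes are provided. `"daily_average"` (default) weights
#' every contributing day pair equally; `"pooled"` weights every valid epoch
#' pair equally. The two agree exactly whenever no epoch is EXCLUDED and all
#' days are complete.
#'
#' @param series a scored [epoch_series()].
#' @param window `"TOTAL"`, `"WEEK1"`, `"WEEK2"` or `"WEEK3"`.
#' @param policy a [filter_policy()] (carried for provenance; eligibility is
#'   checked cohort-wise by [eligibility_filter()]).
#' @param mode `"daily_average"` or `"pooled"`.
#' @return data.frame row with `window`, `sri`, `agreement`, `valid_pairs`,
#'   `day_pairs_used`; `sri` and `agreement` are `NA` when no pair is usable.
#' @export
compute_sri <- function(series, window = "TOTAL", policy = filter_policy(),
                        mode = c("daily_average", "pooled")) {
  mode <- match.arg(mode)
  window <- match.arg(window, c("TOTAL", "WEEK1", "WEEK2", "WEEK3"))
  P <- epochs_per_day(series)
  v <- pair_agreement_vector(series)
  nd <- n_recording_days(series)
  days <- window_days(window, nd)
  sri_from_pairvec(v, P, days, mode, window)
}

window_days <- function(window, nd) {
  if (window == "TOTAL") return(seq_len(nd))
  k <- as.integer(sub("WEEK", "", window))
  (7L * (k - 1L) + 1L):(7L * k)
}

#' Weekly SRIs and week-over-week deltas
#'
#' Computes the SRI for study weeks 1-3 (and the TOTAL window) plus the three
#' delta scores week2 - week1, week3 - week2, week3 - week1. A week the
#' recording does not reach yields `NA`, and any delta involving it is `NA`.
#'
#' @inheritParams compute_sri
#' @return list with `weekly` (data.frame of [compute_sri()] rows for
#'   TOTAL/WEEK1/WEEK2/WEEK3) and `delta` (named numeric vector
#'   `w2_minus_w1`, `w3_minus_w2`, `w3_minus_w1`).
#' @export
weekly_sris <- function(series, policy = filter_policy(),
                        mode = c("daily_average", "pooled")) {
  mode <- match.arg(mode)
  P <- epochs_per_day(series)
  v <- pair_agreement_vector(series)
  nd <- n_recording_days(series)
  weekly <- do.call(rbind, lapply(
    c("TOTAL", "WEEK1", "WEEK2", "WEEK3"),
    function(w) sri_from_pairvec(v, P, window_days(w, nd), mode, w)))
  s <- stats::setNames(weekly$sri, weekly$window)
  delta <- c(w2_minus_w1 = unname(s["WEEK2"] - s["WEEK1"]),
             w3_minus_w2 = unname(s["WEEK3"] - s["WEEK2"]),
             w3_minus_w1 = unname(s["WEEK3"] - s["WEEK1"]))
  list(weekly = weekly, delta = delta)
}

#' Hours of excluded data per recording day
#'
#' @param series an [epoch_series()].
#' @return named numeric vector, one entry per (possibly partial) recording
#'   day, of EXCLUDED hours.
#' @export
excluded_hours_by_day <- function(series) {
  nd <- n_recording_days(series)
  if (nd == 0L) return(stats::setNames(numeric(0), character(0)))
  day <- recording_day(series)
  excl <- series$epochs$state %in% "EXCLUDED"
  counts <- tapply(excl, factor(day, levels = seq_len(nd)), sum)
  counts[is.na(counts)] <- 0
  stats::setNames(as.numeric(counts) * series$epoch_seconds / 3600,
                  paste0("day", seq_len(nd)))
}

#' Days with at least one scored (non-EXCLUDED) epoch
#' @param series an [epoch_series()].
#' @return integer count of recorded days.
#' @export
recorded_days <- function(series) {
  day <- recording_day(series)
  ok <- !(series$epochs$state %in% "EXCLUDED")
  length(unique(day[ok]))
}

#' Apply the study eligibility filter to a cohort
#'
#' Two checks in fixed order. First, participants with fewer than `min_days`
#' recorded days are dropped (`MIN_DAYS`). Then, among the remainder, any
#' participant with `max_excluded_hours_per_day` or more excluded hours on
#' any single day within the first `horizon_days` days is dropped
#' (`EXCLUDED_HOURS`).
#'
#' @param cohort named list of scored [epoch_series()].
#' @param policy a [filter_policy()].
#' @return list with `kept` (character ids) and `dropped` (data.frame
#'   `participant_id`, `reason`, `detail`).
#' @export
eligibility_filter <- function(cohort, policy = filter_policy()) {
  ids <- vapply(cohort, function(s) s$participant_id, character(1))
  kept <- character(0)
  dropped <- list()
  for (i in seq_along(cohort)) {
    s <- cohort[[i]]
    nd <- recorded_days(s)
    if (nd < policy$min_days) {
      dropped[[length(dropped) + 1L]] <- data.frame(
        participant_id = ids[i], reason = "MIN_DAYS",
        detail = sprintf("%d recorded days < %d", nd, policy$min_days),
        stringsAsFactors = FALSE)
      next
    }
    hrs <- excluded_hours_by_day(s)
    horizon <- hrs[seq_len(min(length(hrs), policy$horizon_days))]
    over <- horizon >= policy$max_excluded_hours_per_day
    if (any(over)) {
      d <- which(over)[1]
      dropped[[length(dropped) + 1L]] <- data.frame(
        participant_id = ids[i], reason = "EXCLUDED_HOURS",
        detail = sprintf("%.2f h excluded on day %d", horizon[d], d),
        stringsAsFactors = FALSE)
      next
    }
    kept <- c(kept, ids[i])
  }
  dropped <- if (length(dropped)) do.call(rbind, dropped) else
    data.frame(participant_id = character(0), reason = character(0),
               detail = character(0), stringsAsFactors = FALSE)
  list(kept = kept, dropped = dropped)
}

#' Missing-data sensitivity report
#'
#' For each exclusion threshold (hours per day), counts the participants
#' with at least that many excluded hours on some day within the filter
#' horizon. Counts are monotone non-increasing in the threshold.
#'
#' @param cohort named list of [epoch_series()].
#' @param thresholds hours (default 2, 4, 6).
#' @param horizon_days leading days covered by the check (default 21).
#' @return data.frame with columns `threshold_hours`, `n_participants`.
#' @export
missingness_report <- function(cohort, thresholds = c(2, 4, 6),
                               horizon_days = 21L) {
  worst <- vapply(cohort, function(s) {
    hrs <- excluded_hours_by_day(s)
    horizon <- hrs[seq_len(min(length(hrs), horizon_days))]
    if (length(horizon) == 0L) 0 else max(horizon)
  }, numeric(1))
  data.frame(
    threshold_hours = thresholds,
    n_participants = vapply(thresholds, function(h) sum(worst >= h), numeric(1))
  )
}
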