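#' Sleep/wake scoring policy
#'
#' Parameters of the activity-count sleep/wake scorer. The scorer is the
#' published Actiwatch-style weighted five-epoch kernel: each minute's score
#' is a weighted sum of its own activity count and its four neighbours
#' (weights 1/25, 1/5, 1, 1/5, 1/25), compared against a wake threshold
#' (40 counts, the "medium" sensitivity setting). Vendor implementations are
#' proprietary, so every knob is configurable.
#'
#' @param kernel_weights symmetric numeric weight vector of odd length; the
#'   centre weight must be maximal.
#' @param wake_threshold weighted-count threshold at or above which an epoch
#'   is scored WAKE.
#' @param min_nap_minutes minimum length for a daytime sleep bout to count as
#'   a nap.
#' @param nap_window_start,nap_window_end clock times (`"HH:MM"`) bounding
#'   the daytime nap window; a bout is a nap only if it starts inside
#'   `[start, end)`.
#' @return an object of class `scoring_policy`.
#' @export
scoring_policy <- function(kernel_weights = c(1/25, 1/5, 1, 1/5, 1/25),
                           wake_threshold = 40,
                           min_nap_minutes = 10L,
                           nap_window_start = "08:00",
                           nap_window_end = "20:00") {
  k <- length(kernel_weights)
  if (k %% 2L != 1L) stop("kernel must have odd length", call. = FALSE)
  if (any(kernel_weights < 0)) stop("kernel weights must be >= 0", call. = FALSE)
  if (!isTRUE(all.equal(kernel_weights, rev(kernel_weights)))) {
    stop("kernel weights must be symmetric", call. = FALSE)
  }
  centre <- kernel_weights[(k + 1L) / 2L]
  if (centre < max(kernel_weights)) {
    stop("centre kernel weight must be maximal", call. = FALSE)
  }
  if (wake_threshold <= 0) stop("wake_threshold must be positive", call. = FALSE)
  ws <- parse_clock(nap_window_start)
  we <- parse_clock(nap_window_end)
  if (ws >= we) stop("nap_window_start must precede nap_window_end", call. = FALSE)
  structure(
    list(kernel_weights = kernel_weights,
         wake_threshold = wake_threshold,
         min_nap_minutes = as.integer(min_nap_minutes),
         nap_window_start = nap_window_start,
         nap_window_end = nap_window_end),
    class = "scoring_policy"
  )
}

## "HH:MM" -> minutes past midnight
parse_clock <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  parts <- strsplit(x, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2L) stop("clock time must be 'HH:MM'", call. = FALSE)
  as.numeric(parts[1]) * 60 + as.numeric(parts[2])
}

#' Score sleep/wake states from activity counts
#'
#' Every non-EXCLUDED epoch is scored WAKE when the kernel-weighted activity
#' sum meets the wake threshold, SLEEP otherwise. Where the kernel window
#' overhangs the recording edge or touches EXCLUDED epochs, only the
#' available neighbours are used and their weights are rescaled so the
#' effective total weight matches the full kernel (otherwise epochs next to
#' gaps would be biased toward SLEEP). EXCLUDED epochs stay EXCLUDED.
#'
#' @param series an [epoch_series()] with activity counts.
#' @param policy a [scoring_policy()].
#' @return the series with `state` filled in for all non-EXCLUDED epochs.
#' @export
score_states <- function(series, policy = scoring_policy()) {
  validate_epoch_series(series)
  e <- series$epochs
  n <- nrow(e)
  if (n == 0L) return(series)
  excluded <- e$state %in% "EXCLUDED"
  if (all(excluded)) {
    warning("all epochs EXCLUDED; nothing to score", call. = FALSE)
    return(series)
  }
  w <- policy$kernel_weights
  half <- (length(w) - 1L) %/% 2L
  avail <- as.numeric(!excluded)
  act <- ifelse(excluded | is.na(e$activity), 0, e$activity)

  wsum <- numeric(n)  # available-weighted activity
  wtot <- numeric(n)  # available weight mass
  for (j in seq_along(w)) {
    off <- j - half - 1L
    src <- seq_len(n) + off
    ok <- src >= 1L & src <= n
    idx <- which(ok)
    s <- src[ok]
    wsum[idx] <- wsum[idx] + w[j] * act[s] * avail[s]
    wtot[idx] <- wtot[idx] + w[j] * avail[s]
  }
  full <- sum(w)
  score <- ifelse(wtot > 0, wsum * (full / wtot), 0)

  state <- e$state
  state[!excluded] <- ifelse(score[!excluded] >= policy$wake_threshold,
                             "WAKE", "SLEEP")
  series$epochs$state <- state
  series
}

#' Detect sleep bouts and flag daytime naps
#'
#' Maximal runs of SLEEP epochs become bouts; EXCLUDED epochs break bouts
#' (an unknown state is never asserted asleep). A bout is a nap when its
#' start clock time lies inside the daytime nap window and it lasts at least
#' `min_nap_minutes`; shorter daytime bouts are kept with `is_nap = FALSE`.
#'
#' @param series a scored [epoch_series()].
#' @param policy a [scoring_policy()].
#' @return data.frame with columns `start`, `end`, `minutes`, `is_nap`,
#'   `recording_day` (day of the bout's first epoch).
#' @export
detect_bouts <- function(series, policy = scoring_policy()) {
  e <- series$epochs
  n <- nrow(e)
  empty <- data.frame(start = as.POSIXct(character(0), tz = "UTC"),
                      end = as.POSIXct(character(0), tz = "UTC"),
                      minutes = numeric(0), is_nap = logical(0),
                      recording_day = integer(0))
  if (n == 0L) return(empty)
  if (anyNA(e$state)) stop("series must be scored before bout detection",
                           call. = FALSE)
  is_sleep <- e$state == "SLEEP"
  if (!any(is_sleep)) return(empty)
  r <- rle(is_sleep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  starts <- starts[keep]; ends <- ends[keep]

  epoch_min <- series$epoch_seconds / 60
  minutes <- (ends - starts + 1L) * epoch_min
  start_ts <- e$timestamp[starts]
  end_ts <- start_ts + minutes * 60
  clock <- clock_minutes(start_ts)
  ws <- parse_clock(policy$nap_window_start)
  we <- parse_clock(policy$nap_window_end)
  is_nap <- clock >= ws & clock < we & minutes >= policy$min_nap_minutes
  day <- recording_day(series)[starts]
  data.frame(start = start_ts, end = end_ts, minutes = minutes,
             is_nap = is_nap, recording_day = day)
}

#' Weekly nap minutes
#'
#' Sums nap-bout minutes per study week (recording days 1-7, 8-14, 15-21); a
#' bout belongs to the week containing its first epoch. Weeks the recording
#' never reaches (no scored, non-EXCLUDED epoch in any of the week's days)
#' are `NA`, not zero.
#'
#' @param bouts data.frame from [detect_bouts()].
#' @param series the [epoch_series()] the bouts came from.
#' @param n_weeks number of weeks to report (default 3).
#' @return named numeric vector `week1`, `week2`, ... of nap minutes.
#' @export
weekly_nap_minutes <- function(bouts, series, n_weeks = 3L) {
  day <- recording_day(series)
  scored <- !(series$epochs$state %in% "EXCLUDED") & !is.na(series$epochs$state)
  out <- stats::setNames(rep(NA_real_, n_weeks),
                         paste0("week", seq_len(n_weeks)))
  for (wk in seq_len(n_weeks)) {
    days <- (7L * (wk - 1L) + 1L):(7L * wk)
    if (!any(scored & day %in% days)) next  # week not recorded
    sel <- bouts$is_nap & bouts$recording_day %in% days
    out[wk] <- sum(bouts$minutes[sel])
  }
  out
}
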