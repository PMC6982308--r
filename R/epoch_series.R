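#' @keywords internal
"_PACKAGE"

## Epoch state labels used throughout the package.
EPOCH_STATES <- c("WAKE", "SLEEP", "EXCLUDED")

#' Construct an epoch series
#'
#' An `epoch_series` is one participant's ordered minute-epoch actigraphy
#' record: a regular timestamp grid, a non-negative activity count per epoch,
#' a sleep/wake/excluded state per epoch (possibly unset), and an off-wrist
#' flag. Timestamps are timezone-naive local clock time (stored as POSIXct in
#' UTC so no daylight-saving arithmetic ever applies). Recording days are
#' anchored at the first epoch, not at midnight: day d covers epochs
#' `[(d-1)*P + 1, d*P]` where `P = 86400 / epoch_seconds` epochs per day.
#'
#' @param participant_id single character id.
#' @param timestamp POSIXct vector, strictly increasing on a constant grid.
#' @param activity non-negative numeric counts (NA allowed on EXCLUDED epochs).
#' @param state character vector in `WAKE`, `SLEEP`, `EXCLUDED`, or `NA` for
#'   unscored epochs.
#' @param off_wrist logical; `TRUE` forces state `EXCLUDED`.
#' @param epoch_seconds epoch length in seconds; must divide 86400.
#' @return An object of class `epoch_series`: a list with elements
#'   `participant_id`, `epoch_seconds`, `start`, and `epochs` (a data.frame
#'   with columns `timestamp`, `activity`, `state`, `off_wrist`).
#' @export
epoch_series <- function(participant_id, timestamp, activity,
                         state = NA_character_, off_wrist = FALSE,
                         epoch_seconds = 60L) {
  stopifnot(is.character(participant_id), length(participant_id) == 1L)
  epoch_seconds <- as.integer(epoch_seconds)
  if (epoch_seconds <= 0L || 86400L %% epoch_seconds != 0L) {
    stop("epoch_seconds must be a positive divisor of 86400", call. = FALSE)
  }
  n <- length(timestamp)
  timestamp <- as.POSIXct(timestamp, tz = "UTC")
  activity <- as.numeric(activity)
  state <- rep_len(as.character(state), n)
  off_wrist <- rep_len(as.logical(off_wrist), n)

  if (n > 0) {
    if (anyNA(timestamp)) stop("timestamps contain NA", call. = FALSE)
    d <- diff(as.numeric(timestamp))
    if (any(d <= 0)) stop("timestamps must be strictly increasing", call. = FALSE)
    if (any(abs(d - epoch_seconds) > 1e-6)) {
      stop("timestamps are not on a constant grid of epoch_seconds",
           call. = FALSE)
    }
    bad <- !is.na(state) & !(state %in% EPOCH_STATES)
    if (any(bad)) {
      stop("unknown state value: ", paste(unique(state[bad]), collapse = ", "),
           call. = FALSE)
    }
    if (any(!is.na(activity) & activity < 0)) {
      stop("activity counts must be non-negative", call. = FALSE)
    }
    # off-wrist epochs carry no usable state
    state[off_wrist] <- "EXCLUDED"
  }

  structure(
    list(
      participant_id = participant_id,
      epoch_seconds = epoch_seconds,
      start = if (n > 0) timestamp[1] else as.POSIXct(NA, tz = "UTC"),
      epochs = data.frame(
        timestamp = timestamp,
        activity = activity,
        state = state,
        off_wrist = off_wrist,
        stringsAsFactors = FALSE
      )
    ),
    class = "epoch_series"
  )
}

#' @export
print.epoch_series <- function(x, ...) {
  n <- nrow(x$epochs)
  cat(sprintf(
    "<epoch_series> %s: %d epochs of %ds (%.2f days), %d excluded\n",
    x$participant_id, n, x$epoch_seconds,
    n / epochs_per_day(x),
    sum(x$epochs$state == "EXCLUDED", na.rm = TRUE)
  ))
  invisible(x)
}

#' Epochs per recording day
#' @param series an `epoch_series`.
#' @return integer, `86400 / epoch_seconds` (1440 at the 60-s default).
#' @export
epochs_per_day <- function(series) {
  stopifnot(inherits(series, "epoch_series"))
  86400L %/% series$epoch_seconds
}

#' Number of (possibly partial) recording days spanned by a series
#' @param series an `epoch_series`.
#' @return integer count of recording days, counting a trailing partial day.
#' @export
n_recording_days <- function(series) {
  n <- nrow(series$epochs)
  if (n == 0L) return(0L)
  as.integer(ceiling(n / epochs_per_day(series)))
}

#' Recording-day index of each epoch
#'
#' Day 1 starts at the first epoch of the recording (recordings typically
#' begin mid-day on the enrollment day, so days are never snapped to
#' midnight).
#'
#' @param series an `epoch_series`.
#' @return integer vector, same length as the series.
#' @export
recording_day <- function(series) {
  n <- nrow(series$epochs)
  if (n == 0L) return(integer(0))
  as.integer((seq_len(n) - 1L) %/% epochs_per_day(series)) + 1L
}

## Minutes past local midnight for each epoch (clock time, used for nap
## windows). Works off the stored POSIXct in UTC.
clock_minutes <- function(timestamps) {
  lt <- as.POSIXlt(timestamps, tz = "UTC")
  lt$hour * 60 + lt$min + lt$sec / 60
}

#' Validate an epoch series
#'
#' Re-checks the structural invariants (constant grid, known states,
#' non-negative activity, off-wrist implies EXCLUDED). Called by readers and
#' useful after manual edits.
#'
#' @param series an `epoch_series`.
#' @return the series, invisibly; stops on violation.
#' @export
validate_epoch_series <- function(series) {
  stopifnot(inherits(series, "epoch_series"))
  e <- series$epochs
  if (nrow(e) == 0L) return(invisible(series))
  d <- diff(as.numeric(e$timestamp))
  if (any(abs(d - series$epoch_seconds) > 1e-6)) {
    stop("non-constant epoch spacing", call. = FALSE)
  }
  if (any(!is.na(e$activity) & e$activity < 0)) {
    stop("negative activity count", call. = FALSE)
  }
  if (any(e$off_wrist & e$state != "EXCLUDED")) {
    stop("off-wrist epoch not marked EXCLUDED", call. = FALSE)
  }
  bad <- !is.na(e$state) & !(e$state %in% EPOCH_STATES)
  if (any(bad)) stop("unknown state value", call. = FALSE)
  invisible(series)
}
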