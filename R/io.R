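#' Read a minute-epoch actigraphy CSV
#'
#' Two dialects are supported. `plain` is the package's own tidy layout:
#' header `timestamp,activity[,state][,off_wrist]`, ISO-8601 minute
#' timestamps. `actiware_export` emulates a watch-software export: a metadata
#' preamble terminated by a marker line, then the same epoch table; the
#' marker and column names are configurable because vendor export layouts
#' vary between versions.
#'
#' Gaps in the timestamp grid are filled with `EXCLUDED` epochs (activity
#' `NA`, `off_wrist = TRUE`) so that 24-h lag arithmetic stays pure index
#' arithmetic downstream.
#'
#' @param path file path.
#' @param dialect `"plain"` or `"actiware_export"`.
#' @param participant_id id to attach; default is the file name sans
#'   extension.
#' @param epoch_seconds expected epoch length (default 60).
#' @param preamble_marker for `actiware_export`: the line content that ends
#'   the preamble; the epoch table header follows it.
#' @param columns for `actiware_export`: named character vector mapping the
#'   roles `timestamp`, `activity` and optionally `state`, `off_wrist` to the
#'   exported column names.
#' @return an [epoch_series()].
#' @export
read_epoch_csv <- function(path,
                           dialect = c("plain", "actiware_export"),
                           participant_id = NULL,
                           epoch_seconds = 60L,
                           preamble_marker = "---- Epoch-by-Epoch Data ----",
                           columns = c(timestamp = "Date_Time",
                                       activity = "Activity",
                                       off_wrist = "Off_Wrist")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(participant_id)) {
    participant_id <- sub("\\.[^.]*$", "", basename(path))
  }

  if (dialect == "plain") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character")
    if (!all(c("timestamp", "activity") %in% names(df))) {
      stop("plain dialect requires 'timestamp' and 'activity' columns",
           call. = FALSE)
    }
  } else {
    lines <- readLines(path)
    mark <- which(trimws(lines) == preamble_marker)
    if (length(mark) == 0L) {
      stop("actiware_export preamble marker not found: ", preamble_marker,
           call. = FALSE)
    }
    body <- lines[(mark[1] + 1L):length(lines)]
    df <- utils::read.csv(text = paste(body, collapse = "\n"),
                          stringsAsFactors = FALSE, colClasses = "character")
    need <- columns[c("timestamp", "activity")]
    if (!all(need %in% names(df))) {
      stop("actiware_export table lacks mapped columns: ",
           paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
    }
    out <- data.frame(timestamp = df[[columns[["timestamp"]]]],
                      activity = df[[columns[["activity"]]]],
                      stringsAsFactors = FALSE)
    if (!is.na(columns["state"]) && columns["state"] %in% names(df)) {
      out$state <- df[[columns[["state"]]]]
    }
    if (!is.na(columns["off_wrist"]) && columns["off_wrist"] %in% names(df)) {
      out$off_wrist <- df[[columns[["off_wrist"]]]]
    }
    df <- out
  }

  if (nrow(df) == 0L) {
    return(epoch_series(participant_id, as.POSIXct(character(0), tz = "UTC"),
                        numeric(0), epoch_seconds = epoch_seconds))
  }

  ts <- parse_timestamps(df$timestamp)
  if (anyNA(ts)) {
    stop("malformed timestamp at data row(s): ",
         paste(utils::head(which(is.na(ts)), 5L), collapse = ", "),
         call. = FALSE)
  }
  activity <- suppressWarnings(as.numeric(df$activity))
  if (any(is.na(activity) & !(df$activity %in% c("", "NA")))) {
    stop("malformed activity count at data row(s): ",
         paste(utils::head(which(is.na(activity) &
                                   !(df$activity %in% c("", "NA"))), 5L),
               collapse = ", "), call. = FALSE)
  }
  state <- if ("state" %in% names(df)) {
    s <- toupper(trimws(df$state))
    s[s == ""] <- NA_character_
    s
  } else rep(NA_character_, nrow(df))
  off <- if ("off_wrist" %in% names(df)) {
    tolower(trimws(df$off_wrist)) %in% c("true", "t", "1", "yes")
  } else rep(FALSE, nrow(df))

  # explicit excluded marker forces EXCLUDED regardless of activity
  state[off] <- "EXCLUDED"

  # gap-fill onto the regular grid anchored at the first epoch
  sec <- as.numeric(ts) - as.numeric(ts[1])
  if (any(diff(sec) <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  idx <- sec / epoch_seconds
  if (any(abs(idx - round(idx)) > 1e-6)) {
    stop("timestamps do not fall on a ", epoch_seconds,
         "-s grid anchored at the first epoch", call. = FALSE)
  }
  idx <- as.integer(round(idx)) + 1L
  n <- idx[length(idx)]
  full_ts <- ts[1] + (seq_len(n) - 1L) * epoch_seconds
  full_act <- rep(NA_real_, n)
  full_state <- rep("EXCLUDED", n)
  full_off <- rep(TRUE, n)
  full_act[idx] <- activity
  full_state[idx] <- state
  full_off[idx] <- off

  epoch_series(participant_id, full_ts, full_act, full_state, full_off,
               epoch_seconds = epoch_seconds)
}

## Row-wise tolerant timestamp parser: tries each accepted layout, keeps the
## one that parses the most rows; unparseable rows come back NA.
parse_timestamps <- function(x) {
  fmts <- c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
            "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M")
  best <- NULL
  for (f in fmts) {
    out <- as.POSIXct(strptime(x, f, tz = "UTC"), tz = "UTC")
    if (is.null(best) || sum(!is.na(out)) > sum(!is.na(best))) best <- out
    if (!anyNA(best)) break
  }
  best
}

#' Write an epoch series to CSV
#'
#' Emits the `plain` dialect: header `timestamp,activity,state,off_wrist`,
#' ISO-8601 timestamps, one row per epoch in grid order, so that
#' `read_epoch_csv(write_epoch_csv(s))` reproduces `s` exactly.
#'
#' @param series an [epoch_series()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_epoch_csv <- function(series, path) {
  validate_epoch_series(series)
  e <- series$epochs
  df <- data.frame(
    timestamp = format(e$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    activity = ifelse(is.na(e$activity), "", format(e$activity,
                                                    trim = TRUE,
                                                    scientific = FALSE)),
    state = ifelse(is.na(e$state), "", e$state),
    off_wrist = ifelse(e$off_wrist, "true", "false"),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a daily sleep-diary CSV
#'
#' Expects columns `participant_id`, `date`, plus any of `n_awakenings`,
#' `n_naps_reported`, `caffeinated_drinks`, `mental_exhaustion`,
#' `physical_exhaustion`. Missing fields become `NA`, never zero. Exhaustion
#' scores are 0-10 visual-analog ratings and are validated against that
#' range.
#'
#' @param path file path.
#' @return data.frame with one row per participant-day.
#' @export
read_diary_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  fields <- c("n_awakenings", "n_naps_reported", "caffeinated_drinks",
              "mental_exhaustion", "physical_exhaustion")
  if (nrow(df) == 0L) {
    out <- data.frame(participant_id = character(0),
                      date = as.Date(character(0)))
    for (f in fields) out[[f]] <- numeric(0)
    return(out)
  }
  if (!all(c("participant_id", "date") %in% names(df))) {
    stop("diary requires 'participant_id' and 'date' columns", call. = FALSE)
  }
  if (!any(fields %in% names(df))) {
    stop("diary requires at least one diary field", call. = FALSE)
  }
  out <- data.frame(participant_id = as.character(df$participant_id),
                    date = as.Date(df$date), stringsAsFactors = FALSE)
  for (f in fields) {
    out[[f]] <- if (f %in% names(df)) as.numeric(df[[f]]) else NA_real_
  }
  for (f in c("mental_exhaustion", "physical_exhaustion")) {
    v <- out[[f]]
    if (any(!is.na(v) & (v < 0 | v > 10))) {
      stop(f, " outside the 0-10 scale at row(s): ",
           paste(utils::head(which(!is.na(v) & (v < 0 | v > 10)), 5L),
                 collapse = ", "), call. = FALSE)
    }
  }
  out
}
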