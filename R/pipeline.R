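#' Summarize one participant for cohort analysis
#'
#' Runs bout detection and the SRI windows on a scored series and flattens
#' the result to a single row: total and weekly SRIs, the three delta SRIs,
#' weekly nap minutes and their week3-week1 change.
#'
#' @param series a scored [epoch_series()].
#' @param scoring a [scoring_policy()] (nap window/threshold for bouts).
#' @param filter a [filter_policy()].
#' @param mode SRI averaging mode, see [compute_sri()].
#' @return one-row data.frame.
#' @export
summarize_participant <- function(series, scoring = scoring_policy(),
                                  filter = filter_policy(),
                                  mode = "daily_average") {
  ws <- weekly_sris(series, filter, mode)
  s <- stats::setNames(ws$weekly$sri, ws$weekly$window)
  bouts <- detect_bouts(series, scoring)
  nap <- weekly_nap_minutes(bouts, series)
  data.frame(
    participant_id = series$participant_id,
    sri_total = unname(s["TOTAL"]),
    sri_week1 = unname(s["WEEK1"]), sri_week2 = unname(s["WEEK2"]),
    sri_week3 = unname(s["WEEK3"]),
    delta_w2_w1 = unname(ws$delta["w2_minus_w1"]),
    delta_w3_w2 = unname(ws$delta["w3_minus_w2"]),
    delta_w3_w1 = unname(ws$delta["w3_minus_w1"]),
    nap_week1 = unname(nap["week1"]), nap_week2 = unname(nap["week2"]),
    nap_week3 = unname(nap["week3"]),
    delta_nap_w3_w1 = unname(nap["week3"] - nap["week1"]),
    stringsAsFactors = FALSE
  )
}

#' Build the cohort summary table
#'
#' Applies [summarize_participant()] to every series and joins the covariate
#' table (mood/anxiety flags, weekly exhaustion -> week3-week1 exhaustion
#' deltas, any extra columns).
#'
#' @param series_list named list of scored [epoch_series()].
#' @param covariates optional data.frame keyed by `participant_id`.
#' @inheritParams summarize_participant
#' @return data.frame, one row per participant.
#' @export
build_cohort_table <- function(series_list, covariates = NULL,
                               scoring = scoring_policy(),
                               filter = filter_policy(),
                               mode = "daily_average") {
  tab <- do.call(rbind, lapply(series_list, summarize_participant,
                               scoring = scoring, filter = filter,
                               mode = mode))
  rownames(tab) <- NULL
  if (!is.null(covariates)) {
    tab <- merge(tab, covariates, by = "participant_id", all.x = TRUE,
                 sort = FALSE)
    if (all(c("mexh_week1", "mexh_week3") %in% names(tab))) {
      tab$delta_mexh_w3_w1 <- tab$mexh_week3 - tab$mexh_week1
    }
    if (all(c("pexh_week1", "pexh_week3") %in% names(tab))) {
      tab$delta_pexh_w3_w1 <- tab$pexh_week3 - tab$pexh_week1
    }
  }
  tab[order(tab$participant_id), , drop = FALSE]
}

## Weekly mean (SD) table over the cohort summary, one row per variable.
weekly_summary_table <- function(cohort) {
  vars <- list(SRI = SRI_WEEK_COLS,
               nap_minutes = c("nap_week1", "nap_week2", "nap_week3"))
  rows <- lapply(names(vars), function(v) {
    cols <- vars[[v]]
    if (!all(cols %in% names(cohort))) return(NULL)
    stats_ <- lapply(cols, function(cl) {
      x <- cohort[[cl]]
      c(mean = mean(x, na.rm = TRUE), sd = stats::sd(x, na.rm = TRUE),
        n = sum(!is.na(x)))
    })
    data.frame(variable = v,
               week = 1:3,
               mean = vapply(stats_, `[[`, numeric(1), "mean"),
               sd = vapply(stats_, `[[`, numeric(1), "sd"),
               n = vapply(stats_, `[[`, numeric(1), "n"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full cohort analysis
#'
#' The study pipeline over a cohort of epoch series: (1) score sleep/wake
#' states unless the series already carry them, (2) apply the eligibility
#' filter and build the missingness sensitivity report, (3) summarize each
#' eligible participant (SRI windows, deltas, naps), (4) run the statistical
#' battery: weekly means/SDs, baseline-quartile stratification with
#' repeated-measures ANOVAs and between-quartile delta t-tests, the
#' mood-disorder contrast on total SRI, and the delta correlation table.
#' Steps whose preconditions a small cohort cannot meet (e.g. quartiles at
#' n < 8) are returned as `NULL` rather than failing the run.
#'
#' @param series_list named list of [epoch_series()].
#' @param covariates optional covariate data.frame.
#' @param scoring a [scoring_policy()].
#' @param filter a [filter_policy()].
#' @param mode SRI averaging mode.
#' @param rescore score states from activity even if states are present.
#' @return list with `cohort` (summary table of eligible participants),
#'   `eligibility`, `missingness`, `weekly_table`, `quartiles`,
#'   `rm_anova_bottom`, `rm_anova_top`, `delta_tests`, `mood_contrast`,
#'   `delta_correlations`.
#' @export
analyze_cohort <- function(series_list, covariates = NULL,
                           scoring = scoring_policy(),
                           filter = filter_policy(),
                           mode = "daily_average",
                           rescore = FALSE) {
  scored <- lapply(series_list, function(s) {
    if (rescore || anyNA(s$epochs$state)) score_states(s, scoring) else s
  })
  elig <- eligibility_filter(scored, filter)
  miss <- missingness_report(scored, horizon_days = filter$horizon_days)
  if (length(elig$kept) == 0L) {
    stop("no eligible participants after filtering", call. = FALSE)
  }
  kept <- scored[vapply(scored, function(s)
    s$participant_id %in% elig$kept, logical(1))]
  cohort <- build_cohort_table(kept, covariates, scoring, filter, mode)

  quart <- tryCatch(quartile_stratify(cohort), error = function(e) NULL)
  safely <- function(expr) tryCatch(expr, error = function(e) NULL)
  rm_bottom <- rm_top <- NULL
  delta_tests <- NULL
  if (!is.null(quart)) {
    cc <- cohort[stats::complete.cases(cohort[, SRI_WEEK_COLS]), ]
    rm_bottom <- safely(rm_anova_week(cc[cc$participant_id %in% quart$bottom, ]))
    rm_top <- safely(rm_anova_week(cc[cc$participant_id %in% quart$top, ]))
    delta_tests <- do.call(rbind, lapply(DELTA_COLS, function(d) {
      r <- safely(delta_group_ttest(cohort, quart$bottom, quart$top, d))
      if (is.null(r)) return(NULL)
      cbind(data.frame(delta = d), r,
            data.frame(mean_diff_bottom_minus_top = attr(r, "mean_diff")))
    }))
  }
  list(
    cohort = cohort,
    eligibility = elig,
    missingness = miss,
    weekly_table = weekly_summary_table(cohort),
    quartiles = quart,
    rm_anova_bottom = rm_bottom,
    rm_anova_top = rm_top,
    delta_tests = delta_tests,
    mood_contrast = if ("mood_disorder" %in% names(cohort))
      safely(group_compare_total_sri(cohort)) else NULL,
    delta_correlations = safely(delta_correlations(cohort))
  )
}

#' Write a simulated cohort to disk
#'
#' One epoch CSV per participant (plain dialect) plus `covariates.csv`,
#' `truth.csv` and a YAML manifest recording the scenario and seed, so a
#' simulated cohort can be re-analyzed from files alone.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
simulate_cohort_files <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (s in cohort$series) {
    write_epoch_csv(s, file.path(dir, paste0(s$participant_id, ".csv")))
  }
  utils::write.csv(cohort$covariates, file.path(dir, "covariates.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  writeLines(c("generator: sleepreg", scenario_to_yaml(cohort$scenario)),
             file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Read a cohort directory written by [simulate_cohort_files()]
#'
#' @param dir directory of per-participant epoch CSVs plus
#'   `covariates.csv`.
#' @return list with `series` and `covariates`.
#' @export
read_cohort_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "^P\\d+\\.csv$", full.names = TRUE))
  if (length(files) == 0L) stop("no participant files in ", dir, call. = FALSE)
  series <- lapply(files, read_epoch_csv, dialect = "plain")
  names(series) <- vapply(series, function(s) s$participant_id, character(1))
  cov_path <- file.path(dir, "covariates.csv")
  covariates <- if (file.exists(cov_path))
    utils::read.csv(cov_path, stringsAsFactors = FALSE) else NULL
  list(series = series, covariates = covariates)
}

#' Render a markdown report of an analysis
#'
#' @param result list from [analyze_cohort()].
#' @return character vector of markdown lines.
#' @export
cohort_report <- function(result) {
  fmt <- function(x, d = 2) formatC(x, digits = d, format = "f")
  lines <- c("# Sleep regularity cohort report", "",
             sprintf("Eligible participants: %d (dropped: %d)",
                     nrow(result$cohort), nrow(result$eligibility$dropped)))
  if (nrow(result$eligibility$dropped) > 0) {
    tab <- table(result$eligibility$dropped$reason)
    lines <- c(lines, sprintf("  - %s: %d", names(tab), as.integer(tab)))
  }
  lines <- c(lines, "", "## Weekly summaries (mean, SD, n)", "")
  wt <- result$weekly_table
  lines <- c(lines, sprintf("- %s week %d: %s (%s), n = %d",
                            wt$variable, wt$week, fmt(wt$mean), fmt(wt$sd),
                            as.integer(wt$n)))
  lines <- c(lines, "", "## Missingness sensitivity", "",
             sprintf("- >= %g h on any day: %d participants",
                     result$missingness$threshold_hours,
                     as.integer(result$missingness$n_participants)))
  if (!is.null(result$rm_anova_bottom)) {
    lines <- c(lines, "", "## Baseline-quartile trajectories", "",
               sprintf("- bottom quartile rm-ANOVA: F = %s, p = %.3g, n = %d",
                       fmt(result$rm_anova_bottom$estimate),
                       result$rm_anova_bottom$p_value,
                       result$rm_anova_bottom$n),
               sprintf("- top quartile rm-ANOVA: F = %s, p = %.3g, n = %d",
                       fmt(result$rm_anova_top$estimate),
                       result$rm_anova_top$p_value, result$rm_anova_top$n))
  }
  if (!is.null(result$mood_contrast)) {
    mc <- result$mood_contrast
    lines <- c(lines, "", "## Mood-disorder contrast (total SRI)", "",
               sprintf("- one-way ANOVA: F = %s, p = %.3g, n = %d",
                       fmt(mc$anova$estimate), mc$anova$p_value, mc$anova$n),
               sprintf("- group %s: n = %d, mean = %s, sd = %s",
                       mc$groups$group, mc$groups$n, fmt(mc$groups$mean),
                       fmt(mc$groups$sd)))
  }
  if (!is.null(result$delta_correlations)) {
    dc <- result$delta_correlations
    lines <- c(lines, "", "## Correlations with SRI change (week3 - week1)", "",
               sprintf("- %s: r = %s, p = %.3g, n = %d", dc$analysis,
                       fmt(dc$estimate), dc$p_value, dc$n))
  }
  lines
}
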