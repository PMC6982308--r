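#!/usr/bin/env Rscript
# The cohort statistical battery over the participant summaries from
# 02_compute_sri.R: weekly means/SDs, baseline-quartile trajectories
# (repeated-measures ANOVA per quartile, between-quartile delta t-tests),
# the mood-disorder contrast on total SRI, and Pearson correlations of the
# week3-week1 SRI change against nap and exhaustion changes. Writes a tidy
# statistics CSV and a markdown report.
#
# Usage: Rscript analysis/03_cohort_statistics.R [cohort_dir]

suppressPackageStartupMessages(library(sleepreg))

args <- commandArgs(trailingOnly = TRUE)
cohort_dir <- if (length(args) >= 1) args[1] else "results/cohort"

raw <- read_cohort_dir(cohort_dir)
res <- analyze_cohort(raw$series, raw$covariates, rescore = TRUE)

rows <- list()
add <- function(analysis, r) {
  rows[[length(rows) + 1]] <<- data.frame(
    analysis = analysis, statistic = r$statistic_name, estimate = r$estimate,
    p_value = r$p_value, n = r$n, df = r$df, stringsAsFactors = FALSE)
}
if (!is.null(res$rm_anova_bottom)) add("rm_anova_bottom_quartile", res$rm_anova_bottom)
if (!is.null(res$rm_anova_top)) add("rm_anova_top_quartile", res$rm_anova_top)
if (!is.null(res$delta_tests)) {
  for (i in seq_len(nrow(res$delta_tests))) {
    r <- res$delta_tests[i, ]
    rows[[length(rows) + 1]] <- data.frame(
      analysis = paste0("quartile_ttest_", r$delta), statistic = r$statistic_name,
      estimate = r$estimate, p_value = r$p_value, n = r$n, df = r$df,
      stringsAsFactors = FALSE)
  }
}
if (!is.null(res$mood_contrast)) {
  add("mood_total_sri_anova", res$mood_contrast$anova)
  add("mood_total_sri_ttest", res$mood_contrast$t_test)
}
if (!is.null(res$delta_correlations)) {
  dc <- res$delta_correlations
  for (i in seq_len(nrow(dc))) {
    rows[[length(rows) + 1]] <- data.frame(
      analysis = paste0("delta_cor_", dc$analysis[i]), statistic = "PEARSON_R",
      estimate = dc$estimate[i], p_value = dc$p_value[i], n = dc$n[i],
      df = dc$df[i], stringsAsFactors = FALSE)
  }
}
stats_tab <- do.call(rbind, rows)

dir.create("results", showWarnings = FALSE)
write.csv(stats_tab, "results/cohort_statistics.csv", row.names = FALSE)
writeLines(cohort_report(res), "results/report.md")
write.csv(res$weekly_table, "results/weekly_summaries.csv", row.names = FALSE)

message("Weekly summaries (mean/SD/n):")
print(res$weekly_table, digits = 4)
message("\nStatistics:")
print(stats_tab, digits = 4)
message("\nWrote results/cohort_statistics.csv and results/report.md")
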