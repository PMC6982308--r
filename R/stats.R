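## Uniform row for every statistical result the pipeline emits.
stat_result <- function(name, estimate, p_value, n, df) {
  data.frame(statistic_name = name, estimate = estimate, p_value = p_value,
             n = as.integer(n), df = df, stringsAsFactors = FALSE)
}

## Column names a cohort summary table is expected to carry.
SRI_WEEK_COLS <- c("sri_week1", "sri_week2", "sri_week3")
DELTA_COLS <- c("delta_w2_w1", "delta_w3_w2", "delta_w3_w1")

#' Stratify a cohort by baseline (week 1) SRI quartiles
#'
#' Restricts to participants with SRI present at weeks 1, 2 and 3 (the
#' complete-case set the longitudinal analyses use), sorts by week-1 SRI with
#' participant id as a deterministic tie-break, and returns the bottom and
#' top `floor(n/4)` participants.
#'
#' @param cohort data.frame with `participant_id` and `sri_week1..3`.
#' @return list with `bottom` and `top` character id vectors and `n_complete`.
#' @export
quartile_stratify <- function(cohort) {
  cc <- cohort[stats::complete.cases(cohort[, SRI_WEEK_COLS]), , drop = FALSE]
  n <- nrow(cc)
  if (n < 8L) stop("quartile stratification needs >= 8 complete cases, got ",
                   n, call. = FALSE)
  ord <- order(cc$sri_week1, cc$participant_id)
  ids <- cc$participant_id[ord]
  q <- n %/% 4L
  list(bottom = ids[seq_len(q)], top = ids[(n - q + 1L):n], n_complete = n)
}

#' One-within-factor repeated-measures ANOVA across study weeks
#'
#' F-test of the week effect (3 levels) on repeated measurements of the same
#' participants, computed from the balanced-design sums of squares: total SS
#' is split into subject, week, and residual (subject x week) components and
#' `F = MS_week / MS_residual` with `df = (w - 1, (w - 1)(n - 1))`. No
#' sphericity correction is applied by default; Greenhouse-Geisser is
#' available.
#'
#' @param cohort data.frame; every row must have non-missing values in
#'   `cols`.
#' @param cols the repeated-measure columns, in week order.
#' @param gg logical; apply the Greenhouse-Geisser epsilon correction to the
#'   degrees of freedom and p-value.
#' @return a `stat_result` row (`statistic_name = "F_RM_ANOVA"`).
#' @export
rm_anova_week <- function(cohort, cols = SRI_WEEK_COLS, gg = FALSE) {
  y <- as.matrix(cohort[, cols])
  if (anyNA(y)) {
    bad <- cohort$participant_id[!stats::complete.cases(y)]
    stop("missing weekly values for: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(y); w <- ncol(y)
  if (n < 2L) stop("repeated-measures ANOVA needs >= 2 subjects", call. = FALSE)
  grand <- mean(y)
  ss_subject <- w * sum((rowMeans(y) - grand)^2)
  ss_week <- n * sum((colMeans(y) - grand)^2)
  ss_total <- sum((y - grand)^2)
  ss_resid <- ss_total - ss_subject - ss_week
  df_week <- w - 1L
  df_resid <- (w - 1L) * (n - 1L)
  ms_week <- ss_week / df_week
  ms_resid <- ss_resid / df_resid
  f <- if (ms_resid > 0) ms_week / ms_resid else if (ms_week == 0) 0 else Inf
  d1 <- df_week; d2 <- df_resid
  if (gg) {
    eps <- gg_epsilon(y)
    d1 <- d1 * eps; d2 <- d2 * eps
  }
  p <- if (ms_week == 0 && ms_resid == 0) 1 else stats::pf(f, d1, d2,
                                                           lower.tail = FALSE)
  stat_result("F_RM_ANOVA", f, p, n, sprintf("(%g, %g)", d1, d2))
}

## Greenhouse-Geisser epsilon from the within-subject covariance matrix.
gg_epsilon <- function(y) {
  S <- stats::cov(y)
  w <- ncol(y)
  dbar <- mean(diag(S))
  sbar <- mean(S)
  num <- (w * (dbar - sbar))^2
  den <- (w - 1) * (sum(S^2) - 2 * w * sum(rowMeans(S)^2) + w^2 * sbar^2)
  if (den <= 0) return(1)
  min(1, num / den)
}

#' Pearson correlation with the t-based two-sided p-value
#'
#' Listwise-deletes incomplete pairs, then reports r and the two-sided
#' p-value from the t transform with n - 2 degrees of freedom.
#'
#' @param x,y paired numeric vectors.
#' @return a `stat_result` row (`statistic_name = "PEARSON_R"`).
#' @export
pearson_test <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("Pearson correlation needs >= 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  stat_result("PEARSON_R", unname(ct$estimate), ct$p.value, n,
              sprintf("%d", n - 2L))
}

#' Correlations between SRI change and clinical-variable changes
#'
#' For the week 3 - week 1 SRI delta, computes Pearson correlations against
#' the matching change scores: nap minutes, mental and physical exhaustion,
#' plus any further cohort columns named in `extra_delta_cols`. Each row uses
#' its own pairwise-complete n; rows with fewer than 3 complete pairs are
#' kept with `NA` estimates rather than dropped.
#'
#' @param cohort cohort summary data.frame (see [summarize_participant()]).
#' @param extra_delta_cols optional named character vector: label ->
#'   column holding an additional delta covariate.
#' @param adjust p-adjustment method for the table (default `"none"`,
#'   mirroring an exploratory analysis; `"BH"` available).
#' @return data.frame `analysis`, `estimate`, `p_value`, `n`, `df`.
#' @export
delta_correlations <- function(cohort, extra_delta_cols = NULL,
                               adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  targets <- c(nap_minutes = "delta_nap_w3_w1",
               mental_exhaustion = "delta_mexh_w3_w1",
               physical_exhaustion = "delta_pexh_w3_w1")
  if (!is.null(extra_delta_cols)) targets <- c(targets, extra_delta_cols)
  rows <- lapply(names(targets), function(lbl) {
    col <- targets[[lbl]]
    if (!col %in% names(cohort)) {
      return(data.frame(analysis = lbl, estimate = NA_real_,
                        p_value = NA_real_, n = 0L, df = NA_character_,
                        stringsAsFactors = FALSE))
    }
    x <- cohort$delta_w3_w1
    y <- cohort[[col]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      return(data.frame(analysis = lbl, estimate = NA_real_,
                        p_value = NA_real_, n = sum(ok), df = NA_character_,
                        stringsAsFactors = FALSE))
    }
    r <- pearson_test(x, y)
    data.frame(analysis = lbl, estimate = r$estimate, p_value = r$p_value,
               n = r$n, df = r$df, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust == "BH") out$p_adjusted <- stats::p.adjust(out$p_value, "BH")
  out
}

#' Two-group contrast of total SRI (mood-disorder vs none)
#'
#' One-way ANOVA of total SRI on a two-level grouping, with the equivalent
#' pooled two-sample t-test reported alongside (`F = t^2` for two groups).
#' Rows missing either variable are listwise-deleted.
#'
#' @param cohort cohort summary data.frame.
#' @param group_col logical grouping column (default `"mood_disorder"`).
#' @return list with `anova` and `t_test` `stat_result` rows and `groups`, a
#'   data.frame of per-group n/mean/sd.
#' @export
group_compare_total_sri <- function(cohort, group_col = "mood_disorder") {
  ok <- !is.na(cohort$sri_total) & !is.na(cohort[[group_col]])
  y <- cohort$sri_total[ok]
  g <- factor(cohort[[group_col]][ok], levels = c(FALSE, TRUE))
  if (any(table(g) < 2L)) stop("each group needs >= 2 members", call. = FALSE)
  fit <- stats::anova(stats::lm(y ~ g))
  tt <- stats::t.test(y ~ g, var.equal = TRUE)
  groups <- do.call(rbind, lapply(levels(g), function(lv) {
    v <- y[g == lv]
    data.frame(group = lv, n = length(v), mean = mean(v), sd = stats::sd(v))
  }))
  list(
    anova = stat_result("F_ONEWAY", fit$`F value`[1], fit$`Pr(>F)`[1],
                        length(y), sprintf("(%d, %d)", fit$Df[1], fit$Df[2])),
    t_test = stat_result("T_TWO_GROUP", unname(tt$statistic), tt$p.value,
                         length(y), sprintf("%g", unname(tt$parameter))),
    groups = groups
  )
}

#' Top-vs-bottom quartile t-test on an SRI delta
#'
#' Two-sided two-sample t-test of one delta-SRI score between the bottom and
#' top baseline-SRI quartile groups. Pooled variance by default, Welch
#' optionally.
#'
#' @param cohort cohort summary data.frame.
#' @param bottom,top character id vectors from [quartile_stratify()].
#' @param which_delta one of `"delta_w2_w1"`, `"delta_w3_w2"`,
#'   `"delta_w3_w1"`.
#' @param var_equal pooled variance (`TRUE`, default) or Welch.
#' @return a `stat_result` row (`statistic_name = "T_TWO_GROUP"`) with the
#'   bottom-minus-top mean difference as an attribute `"mean_diff"`.
#' @export
delta_group_ttest <- function(cohort, bottom, top,
                              which_delta = c("delta_w3_w1", "delta_w2_w1",
                                              "delta_w3_w2"),
                              var_equal = TRUE) {
  which_delta <- match.arg(which_delta)
  xb <- cohort[[which_delta]][cohort$participant_id %in% bottom]
  xt <- cohort[[which_delta]][cohort$participant_id %in% top]
  xb <- xb[!is.na(xb)]; xt <- xt[!is.na(xt)]
  if (length(xb) < 2L || length(xt) < 2L) {
    stop("both quartile groups need >= 2 non-missing deltas", call. = FALSE)
  }
  if (stats::var(c(xb - mean(xb), xt - mean(xt))) == 0) {
    stop("zero pooled variance", call. = FALSE)
  }
  tt <- stats::t.test(xb, xt, var.equal = var_equal)
  out <- stat_result("T_TWO_GROUP", unname(tt$statistic), tt$p.value,
                     length(xb) + length(xt),
                     sprintf("%g", unname(tt$parameter)))
  attr(out, "mean_diff") <- mean(xb) - mean(xt)
  out
}
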