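test_that("rm-ANOVA matches the hand table and the aov cross-check", {
  y <- matrix(c(70, 75, 80,
                60, 62, 64,
                80, 79, 81,
                55, 60, 66), nrow = 4, byrow = TRUE)
  cohort <- data.frame(participant_id = paste0("S", 1:4),
                       sri_week1 = y[, 1], sri_week2 = y[, 2],
                       sri_week3 = y[, 3])
  r <- rm_anova_week(cohort)
  # frozen value from the balanced-design sums of squares on this table
  expect_equal(r$estimate, 7.197183098592, tolerance = 1e-9)
  expect_equal(r$p_value, 0.0254637939709, tolerance = 1e-9)
  expect_equal(r$df, "(2, 6)")
  # independent route: aov with an Error stratum
  ora <- rm_anova_aov(y)
  expect_equal(r$estimate, ora$F, tolerance = 1e-9)
  expect_equal(r$p_value, ora$p, tolerance = 1e-9)
})

test_that("rm-ANOVA degenerate and error cases", {
  flat <- data.frame(participant_id = paste0("S", 1:5),
                     sri_week1 = 70:74, sri_week2 = 70:74, sri_week3 = 70:74)
  r <- rm_anova_week(flat)
  expect_equal(r$estimate, 0)
  expect_equal(r$p_value, 1)
  withna <- flat; withna$sri_week2[2] <- NA
  expect_error(rm_anova_week(withna), "S2")
})

test_that("adding a constant to week 2 changes only the week effect", {
  set.seed(401)
  y <- matrix(rnorm(30, 75, 5), nrow = 10)
  base <- data.frame(participant_id = sprintf("S%02d", 1:10),
                     sri_week1 = y[, 1], sri_week2 = y[, 2], sri_week3 = y[, 3])
  shifted <- base; shifted$sri_week2 <- shifted$sri_week2 + 5
  # subject SS identical under the shift
  ss_subj <- function(m) 3 * sum((rowMeans(m) - mean(m))^2)
  expect_equal(ss_subj(as.matrix(base[, 2:4])),
               ss_subj(as.matrix(shifted[, 2:4])), tolerance = 1e-9)
  expect_gt(rm_anova_week(shifted)$estimate, rm_anova_week(base)$estimate)
})

test_that("pearson matches the direct formula on a 10-pair hand set", {
  x <- c(2.1, 3.5, 4.4, 5.0, 6.2, 7.7, 8.1, 9.0, 10.5, 11.2)
  y <- c(5.0, 4.1, 6.3, 5.9, 7.4, 6.8, 9.2, 8.5, 9.9, 11.0)
  r <- pearson_test(x, y)
  ora <- pearson_direct(x, y)
  expect_equal(r$estimate, ora$r, tolerance = 1e-12)
  expect_equal(r$p_value, ora$p, tolerance = 1e-12)
  expect_equal(r$n, 10L)
  # exact linear maps
  expect_equal(pearson_test(x, 2 * x + 3)$estimate, 1)
  expect_equal(pearson_test(x, -x)$estimate, -1)
  # affine invariance
  expect_equal(pearson_test(10 * x - 4, y)$estimate, r$estimate,
               tolerance = 1e-12)
  expect_error(pearson_test(x, rep(1, 10)), "zero variance")
  expect_error(pearson_test(x[1:2], y[1:2]), ">= 3")
})

test_that("two-group one-way ANOVA F equals t squared", {
  cohort <- data.frame(participant_id = paste0("S", 1:6),
                       sri_total = c(70, 72, 75, 64, 66, 61),
                       sri_week1 = NA, sri_week2 = NA, sri_week3 = NA,
                       mood_disorder = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  out <- group_compare_total_sri(cohort)
  expect_equal(out$anova$estimate, out$t_test$estimate^2, tolerance = 1e-9)
  expect_equal(out$anova$p_value, out$t_test$p_value, tolerance = 1e-9)
  expect_equal(out$groups$n, c(3L, 3L))
  set.seed(402)
  big <- data.frame(participant_id = sprintf("S%03d", 1:60),
                    sri_total = rnorm(60, 76, 8),
                    mood_disorder = rep(c(TRUE, FALSE), 30))
  out2 <- group_compare_total_sri(big)
  expect_equal(out2$anova$estimate, out2$t_test$estimate^2, tolerance = 1e-9)
  expect_error(group_compare_total_sri(cohort[1:4, ]), ">= 2")
})

test_that("quartile stratification floors group sizes and orders correctly", {
  set.seed(403)
  n <- 99
  cohort <- data.frame(participant_id = sprintf("S%03d", 1:n),
                       sri_week1 = rnorm(n, 76, 10),
                       sri_week2 = rnorm(n, 76, 10),
                       sri_week3 = rnorm(n, 76, 10))
  q <- quartile_stratify(cohort)
  expect_length(q$bottom, 24L)
  expect_length(q$top, 24L)
  expect_equal(q$n_complete, 99L)
  expect_lte(max(cohort$sri_week1[cohort$participant_id %in% q$bottom]),
             min(cohort$sri_week1[cohort$participant_id %in% q$top]))
  # incomplete cases are excluded before stratifying
  cohort$sri_week3[1:9] <- NA
  q2 <- quartile_stratify(cohort)
  expect_equal(q2$n_complete, 90L)
  expect_length(q2$bottom, 22L)
  # n = 8 edge; error below
  q8 <- quartile_stratify(cohort[10:17, ])
  expect_length(q8$bottom, 2L)
  expect_error(quartile_stratify(cohort[10:16, ]), ">= 8")
})

test_that("delta t-test: identical groups give t = 0, p = 1; shift is detected", {
  cohort <- data.frame(participant_id = sprintf("S%02d", 1:12),
                       delta_w3_w1 = rep(c(1, 2, 3), 4),
                       delta_w2_w1 = 0, delta_w3_w2 = 0)
  bottom <- sprintf("S%02d", 1:6); top <- sprintf("S%02d", 7:12)
  r <- delta_group_ttest(cohort, bottom, top, "delta_w3_w1")
  expect_equal(r$estimate, 0)
  expect_equal(r$p_value, 1)
  expect_error(delta_group_ttest(cohort, bottom, top, "delta_w2_w1"),
               "pooled variance")
  # power at the stylized quartile contrast (+10 shift, SD 6, n 24/24)
  # matches the exact noncentral-t power within Monte-Carlo error
  set.seed(404)
  hits <- replicate(400, {
    co <- data.frame(participant_id = sprintf("S%02d", 1:48),
                     delta_w3_w1 = c(rnorm(24, 10, 6), rnorm(24, 0, 6)))
    delta_group_ttest(co, sprintf("S%02d", 1:24), sprintf("S%02d", 25:48),
                      "delta_w3_w1")$p_value < 1e-4
  })
  ncp <- 10 / (6 * sqrt(2 / 24))
  crit <- qt(1 - 5e-5, 46)
  exact <- 1 - pt(crit, 46, ncp = ncp) + pt(-crit, 46, ncp = ncp)
  expect_lt(abs(mean(hits) - exact), 0.05)
  expect_gt(mean(hits), 0.85)
})

test_that("delta correlation table handles exact maps, nulls, and BH switch", {
  n <- 20
  set.seed(405)
  cohort <- data.frame(participant_id = sprintf("S%02d", 1:n),
                       delta_w3_w1 = rnorm(n),
                       delta_mexh_w3_w1 = rnorm(n),
                       delta_pexh_w3_w1 = rnorm(n))
  cohort$delta_nap_w3_w1 <- -3 * cohort$delta_w3_w1 + 2  # exact negative map
  out <- delta_correlations(cohort)
  expect_equal(out$estimate[out$analysis == "nap_minutes"], -1)
  # all-null column flagged, not crashed
  cohort$delta_nap_w3_w1 <- NA_real_
  out2 <- delta_correlations(cohort)
  expect_true(is.na(out2$estimate[out2$analysis == "nap_minutes"]))
  expect_equal(out2$n[out2$analysis == "nap_minutes"], 0L)
  out3 <- delta_correlations(cohort, adjust = "BH")
  expect_true("p_adjusted" %in% names(out3))
})
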