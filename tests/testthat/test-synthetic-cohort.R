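test_that("a perfectly periodic sleeper has truth-state SRI exactly 100", {
  p <- participant_profile(bedtime_jitter_sd = 0, sleep_duration_sd = 0,
                           nap_rate_per_day = 0, wake_fragmentation_prob = 0)
  s <- generate_participant(p, n_days = 21, seed = 7)
  expect_identical(compute_sri(s, "TOTAL")$sri, 100)
})

test_that("generation is deterministic and leaves the global RNG untouched", {
  p <- participant_profile()
  set.seed(500); before <- rnorm(1)
  s1 <- generate_participant(p, n_days = 3, seed = 99)
  s2 <- generate_participant(p, n_days = 3, seed = 99)
  expect_identical(s1$epochs, s2$epochs)
  set.seed(500)
  expect_identical(rnorm(1), before)   # private stream, global state restored
  # truth states identical with or without activity draws
  s3 <- generate_participant(p, n_days = 3, seed = 99, with_activity = FALSE)
  expect_identical(s3$epochs$state, s1$epochs$state)
})

test_that("mean SRI decreases with bedtime jitter", {
  sri_at <- function(sd, seeds) {
    p <- participant_profile(bedtime_jitter_sd = sd)
    mean(vapply(seeds, function(i)
      compute_sri(generate_participant(p, 10, seed = i,
                                       with_activity = FALSE), "TOTAL")$sri,
      numeric(1)))
  }
  expect_gt(sri_at(0, 1:25), sri_at(60, 1:25))
  expect_gt(sri_at(60, 1:25), sri_at(120, 1:25))
})

test_that("a regularizing jitter trend raises week-3 SRI over week-1", {
  p <- participant_profile(bedtime_jitter_sd = 90, jitter_trend_per_week = -35)
  deltas <- vapply(1:40, function(i) {
    w <- weekly_sris(generate_participant(p, 21, seed = 600 + i,
                                          with_activity = FALSE))
    unname(w$delta["w3_minus_w1"])
  }, numeric(1))
  expect_gt(mean(deltas), 0)
  expect_gt(mean(deltas > 0), 0.8)
})

test_that("generated cohorts have the documented structure and determinism", {
  sc <- scenario_library("filtering_demo")
  g1 <- generate_cohort(sc, seed = 5002)
  g2 <- generate_cohort(sc, seed = 5002)
  expect_identical(g1$covariates, g2$covariates)
  expect_identical(lapply(g1$series, function(s) s$epochs$state),
                   lapply(g2$series, function(s) s$epochs$state))
  expect_equal(nrow(g1$truth), 10L)
  expect_true(all(c("bedtime_jitter_sd", "latent_z", "sri_total") %in%
                    names(g1$truth)))
})

test_that("clean scenario cohorts pass the default eligibility filter", {
  sc <- cohort_scenario(name = "clean", n_participants = 6, n_days = 10)
  g <- generate_cohort(sc, seed = 5003)
  out <- eligibility_filter(g$series)
  expect_length(out$kept, 6L)
})

test_that("scenario library: lookup, unknown names, YAML round-trip", {
  lib <- scenario_library()
  expect_setequal(names(lib),
                  c("regular_baseline", "filtering_demo",
                    "quartile_improvement", "mood_gap", "nap_coupling",
                    "exhaustion_coupling", "null_everything"))
  expect_error(scenario_library("nope"), "unknown scenario")
  for (nm in names(lib)) {
    sc <- lib[[nm]]
    back <- scenario_from_yaml(scenario_to_yaml(sc))
    expect_equal(back, sc, tolerance = 1e-12)
    # and the round-trip must drive generation identically
    if (nm == "filtering_demo") {
      ga <- generate_cohort(sc, n_participants = 10, seed = 1)
      gb <- generate_cohort(back, n_participants = 10, seed = 1)
      expect_identical(ga$truth, gb$truth)
    }
  }
})

test_that("exhaustion coupling reproduces its target correlation on truth deltas", {
  rs <- vapply(1:10, function(i) {
    g <- generate_cohort(scenario_library("exhaustion_coupling"),
                         seed = 5100 + i, with_activity = FALSE)
    d_sri <- g$truth$sri_week3 - g$truth$sri_week1
    d_ex <- g$covariates$mexh_week3 - g$covariates$mexh_week1
    cor(d_sri, d_ex, use = "complete.obs")
  }, numeric(1))
  expect_lt(abs(mean(rs) - (-0.24)), 0.1)
})

test_that("null summary tables carry no week, group, or coupling structure", {
  tab <- simulate_null_summaries(n = 4000, seed = 5200)
  expect_equal(mean(tab$sri_week2 - tab$sri_week1), 0, tolerance = 0.5)
  expect_equal(cor(tab$delta_w3_w1, tab$delta_nap_w3_w1), 0, tolerance = 0.06)
  expect_equal(mean(tab$sri_total[tab$mood_disorder]) -
                 mean(tab$sri_total[!tab$mood_disorder]), 0, tolerance = 0.6)
})

test_that("null generators give uniform p-values for the group contrasts", {
  # summary level at scale: quartile delta t-test on the w3-w2 contrast
  ps <- vapply(1:400, function(i) {
    tab <- simulate_null_summaries(n = 20, seed = 52000 + i)
    q <- quartile_stratify(tab)
    delta_group_ttest(tab, q$bottom, q$top, "delta_w3_w2")$p_value
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)

  # epoch level: mood contrast under null_everything on small cohorts
  sc <- scenario_library("null_everything")
  ps2 <- vapply(1:60, function(i) {
    g <- generate_cohort(sc, n_participants = 16, seed = 53000 + i,
                         with_activity = FALSE, compute_truth_sri = FALSE)
    sri <- vapply(g$series, function(s) compute_sri(s, "TOTAL")$sri,
                  numeric(1))
    tab <- data.frame(participant_id = names(sri), sri_total = unname(sri))
    tab <- merge(tab, g$covariates[, c("participant_id", "mood_disorder")])
    group_compare_total_sri(tab)$anova$p_value
  }, numeric(1))
  expect_gt(stats::ks.test(ps2, "punif")$p.value, 0.01)
})
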