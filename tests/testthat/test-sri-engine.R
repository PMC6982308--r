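test_that("identical days give SRI 100; daily complement gives -100", {
  pat <- day_pattern(690, 430)     # fixed sleep window each day
  s <- make_series(rep(pat, 21))
  r <- compute_sri(s, "TOTAL")
  expect_identical(r$sri, 100)
  expect_equal(r$day_pairs_used, 20L)

  comp <- ifelse(pat == "WAKE", "SLEEP", "WAKE")
  s2 <- make_series(c(rep(c(pat, comp), 5), pat))
  r2 <- compute_sri(s2, "TOTAL")
  expect_identical(r2$sri, -100)
})

test_that("day-pair agreement matches an explicit per-epoch loop", {
  set.seed(301)
  s <- random_state_series(2, p_excluded = 0.1)
  got <- day_pair_agreement(s, 1)
  st <- s$epochs$state
  agree <- 0; k <- 0
  for (t in 1:1440) {
    a <- st[t]; b <- st[t + 1440]
    if (a == "EXCLUDED" || b == "EXCLUDED") next
    k <- k + 1; agree <- agree + (a == b)
  }
  expect_equal(got$valid_pairs, k)
  expect_equal(got$agreement, agree / k)
  # day beyond the recording: null result, no error
  beyond <- day_pair_agreement(s, 5)
  expect_true(is.na(beyond$agreement))
  expect_equal(beyond$valid_pairs, 0L)
})

test_that("pipeline SRI equals the brute-force oracle on random series", {
  set.seed(302)
  for (i in 1:12) {
    nd <- sample(3:21, 1)
    s <- random_state_series(nd, p_excluded = 0.08)
    expect_equal(compute_sri(s, "TOTAL")$sri, sri_bruteforce(s),
                 tolerance = 1e-12)
    wk <- sample(1:3, 1)
    if (7 * (wk - 1) + 1 <= nd) {
      expect_equal(compute_sri(s, paste0("WEEK", wk))$sri,
                   sri_bruteforce(s, (7 * (wk - 1) + 1):(7 * wk)),
                   tolerance = 1e-12)
    }
  }
})

test_that("daily-average and pooled modes agree exactly without exclusions", {
  set.seed(303)
  for (i in 1:6) {
    s <- random_state_series(sample(3:10, 1), p_excluded = 0)
    expect_equal(compute_sri(s, "TOTAL", mode = "daily_average")$sri,
                 compute_sri(s, "TOTAL", mode = "pooled")$sri,
                 tolerance = 1e-12)
    expect_equal(compute_sri(s, "TOTAL", mode = "pooled")$sri,
                 sri_bruteforce_pooled(s), tolerance = 1e-12)
  }
})

test_that("SRI is invariant to state complement and whole-day EXCLUDED prefixes", {
  set.seed(304)
  s <- random_state_series(8, p_excluded = 0.05)
  flip <- s
  flip$epochs$state <- ifelse(s$epochs$state == "WAKE", "SLEEP",
                              ifelse(s$epochs$state == "SLEEP", "WAKE",
                                     "EXCLUDED"))
  expect_equal(compute_sri(flip, "TOTAL")$sri, compute_sri(s, "TOTAL")$sri)

  pre <- make_series(c(rep("EXCLUDED", 2 * 1440), s$epochs$state))
  expect_equal(compute_sri(pre, "TOTAL")$sri, compute_sri(s, "TOTAL")$sri)
})

test_that("sri = 200*agreement - 100 and bounds hold across random series", {
  set.seed(305)
  for (i in 1:10) {
    s <- random_state_series(sample(3:8, 1), p_excluded = 0.1)
    r <- compute_sri(s, "TOTAL")
    expect_equal(r$sri, 200 * r$agreement - 100, tolerance = 1e-9)
    expect_gte(r$sri, -100); expect_lte(r$sri, 100)
  }
})

test_that("weekly SRIs and deltas propagate NA for unreached weeks", {
  set.seed(306)
  s <- random_state_series(10, p_excluded = 0)
  w <- weekly_sris(s)
  sri <- setNames(w$weekly$sri, w$weekly$window)
  expect_false(is.na(sri["WEEK1"]))
  expect_false(is.na(sri["WEEK2"]))   # partial week 2 (days 8-10)
  expect_true(is.na(sri["WEEK3"]))
  expect_true(is.na(w$delta["w3_minus_w1"]))
  expect_true(is.na(w$delta["w3_minus_w2"]))
  expect_equal(unname(w$delta["w2_minus_w1"]),
               unname(sri["WEEK2"] - sri["WEEK1"]))

  # identical days throughout: all weeks 100, all deltas 0
  s2 <- make_series(rep(day_pattern(690, 430), 21))
  w2 <- weekly_sris(s2)
  expect_true(all(w2$weekly$sri == 100))
  expect_true(all(w2$delta == 0))
})

test_that("excluded hours per day match a direct count", {
  states <- rep("WAKE", 6 * 1440)
  states[(4 * 1440 + 1):(4 * 1440 + 240)] <- "EXCLUDED"   # 4 h on day 5
  s <- make_series(states)
  hrs <- excluded_hours_by_day(s)
  expect_equal(unname(hrs), c(0, 0, 0, 0, 4, 0))
  set.seed(307)
  s2 <- random_state_series(5, p_excluded = 0.15)
  hrs2 <- excluded_hours_by_day(s2)
  for (d in 1:5) {
    idx <- ((d - 1) * 1440 + 1):(d * 1440)
    expect_equal(unname(hrs2[d]),
                 sum(s2$epochs$state[idx] == "EXCLUDED") / 60)
  }
})

test_that("eligibility filter drops short then over-excluded participants", {
  clean <- make_series(rep(day_pattern(690, 430), 8), id = "ok")
  short <- make_series(rep(day_pattern(690, 430), 6), id = "short")
  states <- rep(day_pattern(690, 430), 8)
  states[(2 * 1440 + 1):(2 * 1440 + 300)] <- "EXCLUDED"   # 5 h on day 3
  heavy <- make_series(states, id = "heavy")
  out <- eligibility_filter(list(clean, short, heavy))
  expect_equal(out$kept, "ok")
  expect_equal(out$dropped$reason[out$dropped$participant_id == "short"],
               "MIN_DAYS")
  expect_equal(out$dropped$reason[out$dropped$participant_id == "heavy"],
               "EXCLUDED_HOURS")
  # a short AND heavy participant is reported as MIN_DAYS (check order fixed)
  both <- make_series(c(rep(day_pattern(690, 430), 3),
                        rep("EXCLUDED", 1440)), id = "both")
  out2 <- eligibility_filter(list(both))
  expect_equal(out2$dropped$reason, "MIN_DAYS")
})

test_that("exclusions outside the horizon do not drop a participant", {
  states <- rep(day_pattern(690, 430), 23)
  states[(21 * 1440 + 1):(21 * 1440 + 360)] <- "EXCLUDED"  # 6 h on day 22
  s <- make_series(states, id = "late")
  out <- eligibility_filter(list(s))
  expect_equal(out$kept, "late")
})

test_that("missingness report uses >= thresholds and is monotone", {
  states <- rep(day_pattern(690, 430), 8)
  states[1:120] <- "EXCLUDED"                      # exactly 2.0 h on day 1
  s <- make_series(states, id = "m1")
  rep2 <- missingness_report(list(s))
  expect_equal(rep2$n_participants, c(1, 0, 0))    # boundary is >=
  set.seed(308)
  cohort <- lapply(1:8, function(i) random_state_series(8, p_excluded = 0.1,
                                                        id = paste0("r", i)))
  r <- missingness_report(cohort)
  expect_true(all(diff(r$n_participants) <= 0))
})
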