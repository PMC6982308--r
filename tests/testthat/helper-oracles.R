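# Builders and independent oracles shared across the suite.

# Build a minute-epoch series from a state vector (and optional activity).
make_series <- function(states, activity = NULL, id = "T1",
                        start = "2024-01-01 12:00:00") {
  n <- length(states)
  if (is.null(activity)) activity <- ifelse(states == "WAKE", 500, 0)
  activity[states == "EXCLUDED"] <- NA
  epoch_series(id,
               as.POSIXct(start, tz = "UTC") + (seq_len(n) - 1) * 60,
               activity, states, states == "EXCLUDED")
}

# A day's state pattern: asleep [sleep_start, sleep_start + dur) minutes from
# day start, awake elsewhere.
day_pattern <- function(sleep_start, dur, P = 1440) {
  s <- rep("WAKE", P)
  idx <- (sleep_start:(sleep_start + dur - 1)) %% P + 1
  s[idx] <- "SLEEP"
  s
}

# Brute-force SRI: explicit loop over every epoch of every day pair whose
# first day is in `days`, daily-average weighting. Independent of the
# package's vectorized path.
sri_bruteforce <- function(series, days = NULL) {
  st <- series$epochs$state
  P <- 86400 %/% series$epoch_seconds
  n <- length(st)
  nd <- ceiling(n / P)
  if (is.null(days)) days <- seq_len(nd)
  day_means <- c()
  for (d in days) {
    agree <- logical(0)
    k <- 0
    for (t in ((d - 1) * P + 1):min(d * P, n)) {
      t2 <- t + P
      if (t2 > n) next
      a <- st[t]; b <- st[t2]
      if (is.na(a) || is.na(b) || a == "EXCLUDED" || b == "EXCLUDED") next
      k <- k + 1
      agree[k] <- (a == b)
    }
    if (k > 0) day_means <- c(day_means, mean(agree))
  }
  if (length(day_means) == 0) return(NA_real_)
  200 * mean(day_means) - 100
}

# Pooled-weighting brute force (every valid pair equal).
sri_bruteforce_pooled <- function(series) {
  st <- series$epochs$state
  P <- 86400 %/% series$epoch_seconds
  n <- length(st)
  agree <- 0; total <- 0
  for (t in seq_len(max(0, n - P))) {
    a <- st[t]; b <- st[t + P]
    if (is.na(a) || is.na(b) || a == "EXCLUDED" || b == "EXCLUDED") next
    total <- total + 1
    agree <- agree + (a == b)
  }
  if (total == 0) return(NA_real_)
  200 * (agree / total) - 100
}

# Direct-formula Pearson r and two-sided p (t transform, n-2 df).
pearson_direct <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(t), n - 2))
}

# Repeated-measures ANOVA F via stats::aov with an Error stratum -- the
# independent route against the package's direct sums-of-squares version.
rm_anova_aov <- function(y) {
  df <- data.frame(
    val = as.vector(y),
    subj = factor(rep(seq_len(nrow(y)), ncol(y))),
    week = factor(rep(seq_len(ncol(y)), each = nrow(y)))
  )
  fit <- summary(stats::aov(val ~ week + Error(subj), data = df))
  tab <- fit[["Error: Within"]][[1]]
  list(F = tab["week", "F value"], p = tab["week", "Pr(>F)"])
}

# Random valid state series: random lengths, optional EXCLUDED epochs,
# realistic block structure plus scattered noise.
random_state_series <- function(n_days, p_excluded = 0.05, id = "R1") {
  P <- 1440
  n <- n_days * P
  states <- character(0)
  for (d in seq_len(n_days)) {
    st <- sample(1200:1560, 1) %% 1440   # bedtime minute within day
    dur <- sample(300:600, 1)
    states <- c(states, day_pattern(st, dur))
  }
  states <- states[seq_len(n)]
  flip <- runif(n) < 0.02                # scattered state noise
  states[flip] <- ifelse(states[flip] == "WAKE", "SLEEP", "WAKE")
  if (p_excluded > 0) {
    nblk <- rpois(1, n_days * p_excluded * 4)
    for (b in seq_len(nblk)) {
      at <- sample.int(n, 1)
      len <- sample(10:240, 1)
      states[at:min(n, at + len)] <- "EXCLUDED"
    }
  }
  make_series(states, id = id)
}
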