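test_that("participants are excluded below the recorded-days threshold", {
  nine_days <- make_series(unlist(lapply(1:9, function(d) c(rep(10, 5), rep(NA, 1435)))),
                           pid = "P009")
  ten_days <- make_series(unlist(lapply(1:10, function(d) c(rep(10, 5), rep(NA, 1435)))),
                          pid = "P010")
  res <- exclude_short_participants(list(a = nine_days, b = ten_days), min_days = 10)
  expect_identical(res$excluded_ids, "P009")
  expect_length(res$retained, 1)
  expect_identical(res$retained[[1]]$participant_id[1], "P010")
  expect_error(exclude_short_participants(list()), class = "stepcast_config_error")
})

test_that("exclusion counts distinct recorded days on a synthetic cohort", {
  cfg <- generator_preset("default", n_participants = 5, n_days = 15, seed = 61)
  co <- simulate_cohort(cfg)
  # force two participants to be fully missing
  co[[2]] <- co[[2]][0, ]
  co[[4]] <- co[[4]][0, ]
  res <- exclude_short_participants(co, min_days = 1)
  expect_length(res$retained, 3)
  expect_length(res$excluded_ids, 2)
})

test_that("bout detection matches the worked minute-run examples", {
  one <- make_series(c(70, 80, 90, 100, 110))
  b <- detect_bouts(one)
  expect_equal(nrow(b), 1)
  expect_equal(b$duration_min, 5)
  expect_equal(b$start, one$timestamp[1])

  expect_equal(nrow(detect_bouts(make_series(c(70, 80, 90, 100)))), 0)

  broken <- make_series(c(70, 80, 59, 90, 100, 110, 120, 130))
  b2 <- detect_bouts(broken)
  expect_equal(nrow(b2), 1)
  expect_equal(b2$duration_min, 5)
  expect_equal(b2$start, broken$timestamp[4])

  gap <- make_series(c(70, 80, 90, NA, 100, 110, 120, 130, 140))
  expect_equal(detect_bouts(gap)$duration_min, 5)  # gap breaks the first run
  expect_equal(nrow(detect_bouts(make_series(integer(0)))), 0)
})

test_that("bout detection agrees with the brute-force window-scan oracle", {
  set.seed(71)
  for (rep in 1:1000) {
    n <- sample(10:30, 1)
    steps <- sample(c(0, 30, 59, 60, 61, 90, 120), n, replace = TRUE)
    steps[sample(n, floor(n / 5))] <- NA  # timestamp gaps
    s <- make_series(steps)
    got <- detect_bouts(s)
    want <- brute_bouts(s)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want) > 0) {
      expect_equal(as.numeric(got$start) %/% 60, want$start)
      expect_equal(got$duration_min, want$duration)
    }
  }
})

test_that("raising thresholds never increases the bout count (monotonicity)", {
  set.seed(72)
  for (rep in 1:50) {
    s <- make_series(sample(c(0, 59, 60, 80, 120), 40, replace = TRUE))
    n_base <- nrow(detect_bouts(s, 60, 5))
    expect_lte(nrow(detect_bouts(s, 80, 5)), n_base)
    expect_lte(nrow(detect_bouts(s, 60, 7)), n_base)
  }
})

test_that("a bout spanning an hour boundary marks both hours active", {
  # 10-minute bout starting 13:57
  s <- make_series(c(rep(NA, 13 * 60 + 57), rep(100, 10)))
  st <- hourly_states(s)
  expect_equal(nrow(st), 24)
  expect_identical(st$state[14], "ACTIVE")  # 13:00
  expect_identical(st$state[15], "ACTIVE")  # 14:00
  expect_identical(unique(st$state[-c(14, 15)]), "INACTIVE")
})

test_that("hourly states partition the span into ACTIVE/INACTIVE/MISSING", {
  # recorded day with no bouts -> 24 INACTIVE
  s1 <- make_series(c(rep(10, 30), rep(NA, 1410)))
  expect_identical(unique(hourly_states(s1)$state), "INACTIVE")
  # unrecorded day inside the span -> 24 MISSING hours that day
  steps <- c(rep(10, 30), rep(NA, 1440 - 30),  # day 1 recorded
             rep(NA, 1440),                    # day 2 missing
             rep(10, 30))                      # day 3 recorded
  st <- hourly_states(make_series(steps))
  expect_equal(nrow(st), 72)
  expect_identical(unique(st$state[25:48]), "MISSING")
  # partition invariant on simulated data
  cfg <- generator_preset("default", n_participants = 3, n_days = 12, seed = 81)
  for (s in simulate_cohort(cfg)) {
    st <- hourly_states(s)
    span_days <- as.integer(max(as.Date(s$timestamp, tz = "UTC")) -
                              min(as.Date(s$timestamp, tz = "UTC"))) + 1L
    expect_equal(nrow(st), 24 * span_days)
    expect_true(all(st$state %in% c("ACTIVE", "INACTIVE", "MISSING")))
  }
})

test_that("every ACTIVE hour intersects at least one detected bout", {
  cfg <- generator_preset("default", n_participants = 4, n_days = 12, seed = 91)
  for (s in simulate_cohort(cfg)) {
    bouts <- detect_bouts(s)
    st <- hourly_states(s, bouts)
    active_hours <- as.numeric(st$hour[st$state == "ACTIVE"]) %/% 3600
    bout_hours <- unique(unlist(lapply(seq_len(nrow(bouts)), function(b) {
      (as.numeric(bouts$start[b]) %/% 60 + seq_len(bouts$duration_min[b]) - 1) %/% 60
    })))
    expect_true(all(active_hours %in% bout_hours))
  }
})

test_that("inconsistent bouts are rejected", {
  s <- make_series(c(rep(10, 60)))
  fake <- data.frame(participant_id = "P001",
                     start = s$timestamp[1] + 7200, duration_min = 5L)
  expect_error(hourly_states(s, fake), "inconsistent")
})
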