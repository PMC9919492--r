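test_that("generator config validates its invariants", {
  rate <- matrix(0.1, 24, 7)
  expect_s3_class(generator_config(2, hourly_bout_rate = rate), "generator_config")
  expect_error(generator_config(2, hourly_bout_rate = matrix(0.1, 23, 7)),
               class = "stepcast_config_error")
  expect_error(generator_config(2, hourly_bout_rate = -rate),
               class = "stepcast_config_error")
  expect_error(generator_config(2, hourly_bout_rate = rate, missing_day_prob = 1.2),
               class = "stepcast_config_error")
  expect_error(generator_config(2, hourly_bout_rate = rate,
                                bout_duration = list(family = "lognormal",
                                                     meanlog = 2, sdlog = 0.7, floor = 3)),
               class = "stepcast_config_error")
  expect_error(generator_config(2, hourly_bout_rate = rate,
                                active_cadence = list(family = "shifted_poisson",
                                                      min = 40, lambda = 10)),
               class = "stepcast_config_error")
})

test_that("zero bout rate yields no walking-cadence minutes; full missingness yields no records", {
  quiet <- generator_config(2, n_days = 8, hourly_bout_rate = matrix(0, 24, 7),
                            missing_day_prob = 0, seed = 5)
  s <- simulate_participant(quiet, 1)
  expect_gt(nrow(s), 0)
  expect_true(all(s$steps >= 1 & s$steps < 60))
  expect_equal(nrow(detect_bouts(s)), 0)

  gone <- generator_config(2, n_days = 8, hourly_bout_rate = matrix(0.2, 24, 7),
                           missing_day_prob = 1, seed = 5)
  expect_equal(nrow(simulate_participant(gone, 1)), 0)
})

test_that("series timestamps are strictly increasing at minute resolution with non-negative steps", {
  cfg <- generator_preset("default", n_participants = 3, n_days = 12, seed = 11)
  for (i in 1:3) {
    s <- simulate_participant(cfg, i)
    expect_true(all(diff(as.numeric(s$timestamp)) >= 60))
    expect_true(all(as.numeric(s$timestamp) %% 60 == 0))
    expect_true(all(s$steps >= 0))
  }
})

test_that("cohorts are deterministic in the seed and differ across seeds", {
  cfg <- generator_preset("default", n_participants = 3, n_days = 10, seed = 21)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(lapply(a, unclass), lapply(b, unclass))
  cfg2 <- generator_preset("default", n_participants = 3, n_days = 10, seed = 22)
  c2 <- simulate_cohort(cfg2)
  expect_false(identical(lapply(a, `[[`, "timestamp"), lapply(c2, `[[`, "timestamp")))
  expect_length(simulate_cohort(generator_preset("default", n_participants = 0)), 0)
})

test_that("participant streams are stable under cohort-size changes (child-seed discipline)", {
  small <- generator_preset("default", n_participants = 2, n_days = 10, seed = 33)
  big <- generator_preset("default", n_participants = 5, n_days = 10, seed = 33)
  expect_identical(unclass(simulate_participant(small, 2)),
                   unclass(simulate_participant(big, 2)))
})

test_that("cohort summary matches a hand-counted single-bout fixture", {
  s <- make_series(c(rep(NA, 30), rep(100, 10)))  # one 10-min bout at 00:30
  sm <- summarize_cohort(list(s))
  get <- function(stat) sm$mean[sm$statistic == stat]
  expect_equal(get("bouts_per_day"), 1)
  expect_equal(get("mean_bout_length_min"), 10)
  expect_equal(get("walking_hours_per_day"), 1)  # 00:30-00:39 touches one hour
  expect_equal(get("recorded_min_per_day"), 10)
  expect_equal(get("missing_day_fraction"), 0)
  # all-missing cohort
  empty <- make_series(rep(NA, 5))
  sm2 <- summarize_cohort(list(empty))
  expect_equal(sm2$mean[sm2$statistic == "missing_day_fraction"], 1)
  expect_error(summarize_cohort(list()), class = "stepcast_config_error")
})

test_that("null and structured presets share the marginal rate but differ in concentration", {
  nullc <- generator_preset("null")
  strc <- generator_preset("structured")
  expect_equal(dim(nullc$hourly_bout_rate), c(24L, 7L))
  expect_lt(diff(range(nullc$hourly_bout_rate)), 1e-12)  # flat
  expect_gt(max(strc$hourly_bout_rate), 8 * mean(strc$hourly_bout_rate))
  # week-average expected starts/day agree with the preset's target
  expect_equal(mean(colSums(nullc$hourly_bout_rate)), 2.6, tolerance = 1e-6)
  expect_equal(mean(colSums(strc$hourly_bout_rate)), 2.6, tolerance = 1e-6)
})

test_that("cohort round-trips exactly through the delimited-text format", {
  cfg <- generator_preset("default", n_participants = 2, n_days = 8, seed = 41)
  co <- simulate_cohort(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_identical(names(back), names(co))
  for (nm in names(co)) {
    expect_equal(back[[nm]]$timestamp, co[[nm]]$timestamp)
    expect_identical(back[[nm]]$steps, co[[nm]]$steps)
  }
})
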