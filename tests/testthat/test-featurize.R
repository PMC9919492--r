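test_that("calendar encoding one-hots hour, weekday, month and day-of-month", {
  # 2015-08-03 14:00 UTC is a Monday, August 3rd
  v <- encode_time(as.POSIXct("2015-08-03 14:00:00", tz = "UTC"))
  expect_length(v, 74)
  expect_equal(sum(v), 4)
  expect_equal(which(v == 1), c(1 + 14, 25 + 0, 32 + 7, 44 + 2))
  # any anchor has exactly four ones
  set.seed(101)
  anchors <- UTC0 + sample.int(4000, 25) * 3600
  m <- encode_time(anchors)
  expect_true(all(rowSums(m) == 4))
  # 24 h apart: same hour block, shifted weekday block
  a <- as.POSIXct("2015-08-03 09:00:00", tz = "UTC")
  va <- encode_time(a); vb <- encode_time(a + 86400)
  expect_equal(va[1:24], vb[1:24])
  expect_equal(which(vb[25:31] == 1), which(va[25:31] == 1) + 1)
})

test_that("history encoding pads pre-span hours as MISSING and indexes lags correctly", {
  st <- make_states(rep("INACTIVE", 900))
  # anchor at the very start of the span: all 840 triples MISSING-hot
  h0 <- encode_history(st, st$hour[1])
  expect_length(h0, 2520)
  expect_equal(sum(h0), 840)
  expect_true(all(h0[seq(3, 2520, by = 3)] == 1))  # MISSING slot of every triple
  # fully observed inactive history: all INACTIVE-hot
  h1 <- encode_history(st, st$hour[841])
  expect_true(all(h1[seq(2, 2520, by = 3)] == 1))
  # single ACTIVE hour exactly 840 hours before the anchor -> last triple
  st2 <- make_states(c("ACTIVE", rep("INACTIVE", 899)))
  h2 <- encode_history(st2, st2$hour[841])
  expect_equal(h2[3 * 839 + 1], 1)                      # lag-840 ACTIVE slot
  expect_true(all(h2[seq(2, 3 * 839, by = 3)] == 1))    # other lags INACTIVE
})

test_that("outcome labels merge the 3-hour window with ACTIVE dominating MISSING", {
  st <- make_states(c("INACTIVE", "ACTIVE", "MISSING", "INACTIVE", "INACTIVE",
                      "INACTIVE", "MISSING", "MISSING", "MISSING"))
  expect_equal(label_outcome(st, st$hour[1]), 1L)   # [INACTIVE, ACTIVE, MISSING]
  expect_equal(label_outcome(st, st$hour[4]), 0L)   # all INACTIVE
  expect_true(is.na(label_outcome(st, st$hour[7]))) # all MISSING -> skip
  expect_true(is.na(label_outcome(st, st$hour[8]))) # window leaves the span
  expect_equal(label_outcome(st, st$hour[5], horizon = 1), 0L)
})

test_that("instance building matches hand counts on two fully recorded days", {
  st <- make_states(rep("INACTIVE", 48))
  inst <- build_instances(st)
  expect_equal(nrow(inst$features), 46)  # last 2 anchors lack a full window
  expect_true(all(inst$label == 0))
  # one bout at 10:30 of day 1 -> ACTIVE hour 10:00; labels 1 at anchors 08-10
  st2 <- make_states(c(rep("INACTIVE", 10), "ACTIVE", rep("INACTIVE", 37)))
  inst2 <- build_instances(st2)
  expect_equal(nrow(inst2$features), 46)
  expect_equal(which(inst2$label == 1), 9:11)  # anchors 08:00, 09:00, 10:00
  # all-missing participant contributes nothing
  st3 <- rbind(st2, make_states(rep("MISSING", 48), pid = "P002"))
  inst3 <- build_instances(st3)
  expect_equal(nrow(inst3$features), 46)
  expect_identical(unique(inst3$participant_id), "P001")
})

test_that("instance counts and labels equal the enumeration oracle on random short cohorts", {
  set.seed(111)
  for (rep in 1:40) {
    n_days <- sample(2:5, 1)
    states <- sample(c("ACTIVE", "INACTIVE", "MISSING"), n_days * 24,
                     replace = TRUE, prob = c(0.1, 0.6, 0.3))
    st <- make_states(states)
    want <- enum_instances(states)
    if (length(want$anchors) == 0) {
      expect_error(build_instances(st), class = "stepcast_config_error")
      next
    }
    inst <- build_instances(st)
    expect_equal(nrow(inst$features), length(want$anchors))
    expect_equal(inst$label, want$labels)
    expect_equal(as.integer((as.numeric(inst$anchor) -
                               as.numeric(st$hour[1])) / 3600) + 1L, want$anchors)
  }
})

test_that("every feature vector carries exactly 844 ones in the declared layout", {
  inst <- small_structured_instances()
  expect_equal(ncol(inst$features), 2594)
  expect_true(all(Matrix::rowSums(inst$features) == 844))
  lay <- feature_layout()
  expect_equal(lay$n_features, 2594)
  expect_equal(sum(lay$blocks$width), 2594)
  # one 1 per temporal block and per lag triple, checked on a sample row
  v <- as.numeric(inst$features[1, ])
  expect_equal(sum(v[1:24]), 1)
  expect_equal(sum(v[25:31]), 1)
  expect_equal(sum(v[32:43]), 1)
  expect_equal(sum(v[44:74]), 1)
  triples <- matrix(v[75:2594], nrow = 3)
  expect_true(all(colSums(triples) == 1))
})

test_that("class imbalance on the null preset has inactive far outnumbering active", {
  cfg <- generator_preset("null", n_participants = 5, n_days = 20, seed = 121)
  pre <- preprocess_cohort(simulate_cohort(cfg), min_days = 5)
  inst <- build_instances(pre$states)
  expect_gt(inst$provenance$n_inactive, 2 * inst$provenance$n_active)
})

test_that("instance sets round-trip through the on-disk sparse format", {
  inst <- small_structured_instances()
  dir <- withr::local_tempdir()
  write_instances(inst, file.path(dir, "inst"))
  back <- read_instances(file.path(dir, "inst"))
  expect_equal(dim(back$features), dim(inst$features))
  expect_true(all(back$features == inst$features))
  expect_identical(back$label, inst$label)
  expect_identical(back$participant_id, inst$participant_id)
  expect_equal(back$anchor, inst$anchor)
  expect_equal(back$provenance$horizon, inst$provenance$horizon)
})
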