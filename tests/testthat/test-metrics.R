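test_that("total sleep time sums non-wake epochs", {
  h <- hyp_of(list("N2", 240), list("N3", 120), list("REM", 60),
              list("N0", 60))
  expect_equal(total_sleep_time(h), 3.5)
  expect_equal(total_sleep_time(hyp_of(list("N0", 10))), 0)
  # permutation invariance
  set.seed(1)
  hp <- hypnogram(sample(unclass(h)))
  expect_equal(total_sleep_time(hp), 3.5)
})

test_that("stage percentages are fractions of TST and sum to 100", {
  h <- hyp_of(list("N2", 240), list("N3", 120), list("REM", 60),
              list("N0", 60))
  pct <- stage_percentages(h)
  expect_equal(pct[["N2_pct"]], 240 / 420 * 100)
  expect_equal(sum(pct), 100, tolerance = 1e-9)
  single <- stage_percentages(hyp_of(list("N2", 50)))
  expect_equal(single[["N2_pct"]], 100)
  expect_error(stage_percentages(hyp_of(list("N0", 5))), "TST = 0")
})

test_that("sleep efficiency follows TST/TSC and clamps at 100", {
  expect_equal(round(sleep_efficiency(7.61, 9), 2), 84.56)
  expect_equal(sleep_efficiency(0, 9), 0)
  expect_equal(sleep_efficiency(9, 9), 100)
  expect_warning(se <- sleep_efficiency(10, 9), "clamped")
  expect_equal(se, 100)
  h <- hyp_of(list("N2", 120))  # 1 h of N2
  expect_equal(sleep_efficiency(h, tsc = 2), 50)
})

test_that("sleep onset latency is measured from lights-off to first N2", {
  h <- hyp_of(list("N0", 52), list("N2", 100))
  expect_equal(sleep_onset_latency(h), 26)
  expect_equal(sleep_onset_latency(hyp_of(list("N2", 10))), 0)
  h_off <- hypnogram(c(rep("N0", 62), rep("N2", 20)),
                     lights_off_epoch = 10)
  expect_equal(sleep_onset_latency(h_off), 26)
  expect_error(sleep_onset_latency(hyp_of(list("N0", 5), list("N1", 5))),
               "no N2")
})

test_that("REM latency runs from first N1 to first REM", {
  h <- hypnogram(c(rep("N0", 20), rep("N1", 10), rep("N2", 116),
                   rep("REM", 20)))
  rl <- rem_latency(h)
  expect_equal(rl$RL, 126 * 30 / 3600)
  h2 <- hyp_of(list("N1", 1), list("REM", 10))
  expect_equal(rem_latency(h2)$RL, 1 / 120)
  # RL% uses the printed RL/TST formula
  expect_equal(rl$RL_pct, rl$RL / total_sleep_time(h) * 100)
  expect_error(rem_latency(hyp_of(list("N2", 10))), "undefined")
})

test_that("awakenings count interior wake bouts only", {
  h <- hyp_of(list("N0", 10), list("N2", 100), list("N0", 4),
              list("N3", 100))
  expect_equal(awakening_count(h), 1)
  expect_equal(awakening_count(hyp_of(list("N0", 5), list("N2", 50))), 0)
  trailing <- hyp_of(list("N2", 50), list("N0", 20))
  expect_equal(awakening_count(trailing), 0)
  expect_warning(wn <- awakening_count(hyp_of(list("N0", 5))), "no sleep")
  expect_equal(wn, 0L)
})

test_that("metric invariance to epoch-duration re-parameterization", {
  s <- c(rep("N0", 10), rep("N2", 50), rep("N0", 2), rep("N3", 30))
  h30 <- hypnogram(s, epoch_sec = 30)
  h15 <- hypnogram(rep(s, each = 2), epoch_sec = 15)
  expect_equal(total_sleep_time(h30), total_sleep_time(h15))
  expect_equal(stage_percentages(h30), stage_percentages(h15))
  expect_equal(sleep_onset_latency(h30), sleep_onset_latency(h15))
})

test_that("sleep_metrics assembles the per-night table", {
  p <- architecture_params()
  h <- simulate_hypnogram(p, seed = 77)
  m <- sleep_metrics(h, tsc = 9)
  expect_equal(names(m), c("TST", "N1_pct", "N2_pct", "N3_pct", "REM_pct",
                           "SE", "SOL", "RL", "RL_pct", "WN", "TSC"))
  expect_equal(m$SE, m$TST / 9 * 100)
  expect_equal(m$N1_pct + m$N2_pct + m$N3_pct + m$REM_pct, 100,
               tolerance = 1e-9)
})
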