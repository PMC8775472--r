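test_that("architecture parameters validate transition weights", {
  expect_s3_class(architecture_params(), "architecture_params")
  bad <- matrix(0, 5, 5)
  expect_error(architecture_params(transition = bad), "normalizable")
  neg <- architecture_params()$transition
  neg[1, 2] <- -1
  expect_error(architecture_params(transition = neg), "non-negative")
})

test_that("a degenerate SOL distribution pins sleep onset exactly", {
  p <- architecture_params(sol_mean = 26, sol_sd = 0)
  h <- simulate_hypnogram(p, seed = 1)
  expect_length(h, 9 * 120)
  expect_equal(match("N2", unclass(h)) - 1L, 52L)   # 0-based epoch 52
  expect_equal(sleep_onset_latency(h), 26)
})

test_that("hypnogram simulation is deterministic and well-formed", {
  p <- architecture_params(tsc_hours = 3)
  h1 <- simulate_hypnogram(p, seed = 7)
  h2 <- simulate_hypnogram(p, seed = 7)
  expect_identical(unclass(h1), unclass(h2))
  expect_length(h1, 360)
  expect_true(all(unclass(h1) %in% stage_levels()))
  # at least one complete N1 -> N2 -> N3 -> REM progression
  s <- unclass(h1)
  i1 <- match("N1", s)
  i2 <- i1 + match("N2", s[-seq_len(i1)])
  i3 <- i2 + match("N3", s[-seq_len(i2)])
  i4 <- i3 + match("REM", s[-seq_len(i3)])
  expect_false(anyNA(c(i1, i2, i3, i4)))
})

test_that("dwell calibration hits a 25% N3 target within Monte-Carlo error", {
  p <- calibrate_n3_dwell(architecture_params(), 25)
  set.seed(31)
  n3 <- replicate(200,
    stage_percentages(simulate_hypnogram(p))[["N3_pct"]])
  expect_lt(abs(mean(n3) - 25), 2)
})

test_that("synthesized EEG realizes the stage's dominant band", {
  rate <- 100
  h_n3 <- hypnogram(rep("N3", 6))
  rec <- synthesize_eeg(h_n3, rate = rate, seed = 41)
  ep <- epoch_record(rec, "Pz-Oz")
  bands <- list(delta = c(1.5, 4), theta = c(4, 8), alpha = c(8, 13),
                beta = c(13, 25), gamma = c(25, 40))
  for (e in seq_len(nrow(ep))) {
    pw <- sapply(bands, function(b)
      oracle_band_power(ep[e, ], rate, b[1], b[2]))
    expect_equal(names(which.max(pw)), "delta")
  }
  h_n0 <- hypnogram(rep("N0", 6))
  rec0 <- synthesize_eeg(h_n0, rate = rate, seed = 42)
  ep0 <- epoch_record(rec0, "Pz-Oz")
  for (e in seq_len(nrow(ep0))) {
    pw <- sapply(bands, function(b)
      oracle_band_power(ep0[e, ], rate, b[1], b[2]))
    expect_equal(names(which.max(pw)), "alpha")
  }
})

test_that("EEG synthesis is reproducible and continuous across epochs", {
  h <- hypnogram(c(rep("N2", 2), rep("N3", 2)))
  r1 <- synthesize_eeg(h, seed = 43)
  r2 <- synthesize_eeg(h, seed = 43)
  expect_identical(r1$signals, r2$signals)
  expect_named(as.data.frame(r1$signals), c("Pz-Oz", "EOG1", "EOG2"))
  # no amplitude discontinuity at the N2 -> N3 boundary beyond noise scale
  x <- r1$signals[, "Pz-Oz"]
  jump <- abs(diff(x))[6000]
  expect_lt(jump, 6 * sd(abs(diff(x))) + median(abs(diff(x))))
  expect_error(synthesize_eeg(h, rate = 50), "100")
})

test_that("cohorts carry the injected effect and reproducible seeds", {
  base <- architecture_params(tsc_hours = 3)
  null_params <- apply_group_effect(base, group_effect())
  expect_equal(null_params, base)
  co <- simulate_cohort(21, 20, base, seed = 5)
  expect_length(co, 41)
  expect_equal(sum(sapply(co, `[[`, "group") == "exposed"), 21)
  co2 <- simulate_cohort(21, 20, base, seed = 5)
  expect_identical(lapply(co, `[[`, "hypnogram"),
                   lapply(co2, `[[`, "hypnogram"))
  expect_error(simulate_cohort(1, 5, base), "at least 2")
})

test_that("a positive N3 dwell shift raises exposed ground-truth N3%", {
  base <- architecture_params()
  eff <- group_effect(delta_n3_dwell = 5)
  co <- simulate_cohort(25, 25, base, eff, seed = 9)
  m <- cohort_metrics(co)
  expect_gt(mean(m$N3_pct[m$group == "exposed"]),
            mean(m$N3_pct[m$group == "sham"]))
})

test_that("group effects must keep parameters in their valid domain", {
  base <- architecture_params()
  expect_error(apply_group_effect(base, group_effect(delta_n3_dwell = -50)),
               "valid domain")
  # SE shift shrinks non-sleep time parameters
  shifted <- apply_group_effect(base, group_effect(delta_se = 2))
  expect_lt(shifted$sol_mean, base$sol_mean)
  expect_lte(shifted$dwell[["N0"]], base$dwell[["N0"]])
})

test_that("cohort manifests round-trip to disk", {
  co <- simulate_cohort(2, 2, architecture_params(tsc_hours = 1), seed = 3)
  dir <- withr::local_tempdir()
  mpath <- write_cohort(co, dir)
  man <- read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), 4)
  h <- read_hypnogram(file.path(dir, man$hypnogram[1]))
  expect_equal(unclass(h), unclass(co[[1]]$hypnogram), ignore_attr = TRUE)
})
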