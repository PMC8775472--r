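make_rec <- function(n = 6000, rate = 100, channels = c("Pz-Oz")) {
  sig <- sapply(channels, function(ch) rnorm(n))
  eeg_recording(sig, rate = rate, channels = channels)
}

test_that("resampling halves sample counts, rejects upsampling, is identity", {
  rec <- make_rec(12000, rate = 200)
  out <- resample_recording(rec, 100)
  expect_equal(nrow(out$signals), 6000)
  expect_equal(out$rate, 100)
  rec100 <- make_rec(1000, 100)
  same <- resample_recording(rec100, 100)
  expect_identical(same$signals, rec100$signals)
  expect_error(resample_recording(make_rec(1000, 100), 200), "upsampling")
})

test_that("resampling preserves the dominant frequency of a tone", {
  t <- seq(0, 60 - 1 / 500, by = 1 / 500)
  rec <- eeg_recording(sin(2 * pi * 10 * t), rate = 500, channels = "C3")
  out <- resample_recording(rec, 100)
  x <- out$signals[, 1]
  P <- abs(fft(x))^2
  f <- (seq_along(x) - 1) * 100 / length(x)
  dom <- f[f <= 50][which.max(P[f <= 50])]
  expect_equal(dom, 10, tolerance = 0.1)
})

test_that("band-pass meets its response contract and is zero-phase", {
  rate <- 100
  t <- seq(0, 120 - 1 / rate, by = 1 / rate)
  gain_at <- function(freq) {
    rec <- eeg_recording(sin(2 * pi * freq * t), rate, channels = "C3")
    y <- bandpass_recording(rec)$signals[, 1]
    mid <- y[3000:9000]
    max(abs(mid))
  }
  expect_gt(20 * log10(gain_at(10)), -1)    # passband within 1 dB
  expect_lt(20 * log10(gain_at(0.1)), -20)  # stopband
  expect_lt(20 * log10(gain_at(49)), -20)
  # zero signal maps to zero; no phase shift of a passband tone
  z <- bandpass_recording(eeg_recording(numeric(3000), rate,
                                        channels = "C3"))
  expect_equal(max(abs(z$signals)), 0)
  rec <- eeg_recording(sin(2 * pi * 10 * t), rate, channels = "C3")
  y <- bandpass_recording(rec)$signals[, 1]
  lagcor <- sapply(-3:3, function(l) {
    idx <- 3000:9000
    cor(y[idx], sin(2 * pi * 10 * t)[idx + l])
  })
  expect_equal(which.max(lagcor), 4L)       # best alignment at lag 0
  expect_error(bandpass_recording(make_rec(), high = 60), "Nyquist")
})

test_that("channel repair averages neighbours with the requested weights", {
  n <- 500
  sig <- cbind(C3 = rep(2, n), C4 = rep(4, n), Cz = rnorm(n))
  rec <- eeg_recording(sig, 100)
  out <- repair_channel(rec, "Cz", c("C3", "C4"), weights = c(1, 1))
  expect_equal(unname(out$signals[, "Cz"]), rep(3, n))
  out1 <- repair_channel(rec, "Cz", "C3")
  expect_equal(out1$signals[, "Cz"], out1$signals[, "C3"])
  sig2 <- cbind(O1 = rep(4, n), O2 = rep(0, n), Oz = rnorm(n))
  out2 <- repair_channel(eeg_recording(sig2, 100), "Oz", c("O1", "O2"),
                         weights = c(0.75, 0.25))
  expect_equal(unname(out2$signals[, "Oz"]), rep(3, n))
  expect_error(repair_channel(rec, "Cz", "F9"), "no neighbouring")
})

test_that("ICA removes an EOG-identical component and is near-idempotent", {
  set.seed(11)
  n <- 3000
  # non-Gaussian sources (ICA needs non-Gaussianity to separate):
  # heavy-tailed neural activity, sparse blink-like ocular bursts
  neural <- cbind(rt(n, 4), rt(n, 4), rt(n, 4))
  t_ax <- seq_len(n) / 100
  eog <- rowSums(sapply(c(4, 9, 13, 19, 25), function(t0)
    80 * exp(-((t_ax - t0) / 0.3)^2)))
  mix <- neural %*% matrix(c(1, .3, .2, .4, 1, .3, .2, .5, 1), 3) +
    outer(eog, c(2.5, 1.5, 1.0))
  sig <- cbind(mix, eog + rnorm(n, sd = 0.05))
  colnames(sig) <- c("C3", "C4", "Pz", "EOG1")
  rec <- eeg_recording(sig, 100)
  out <- remove_eog_artifacts(rec, threshold = 0.8)
  for (ch in c("C3", "C4", "Pz")) {
    expect_lt(abs(cor(out$signals[, ch], eog)), 0.8)
    expect_lte(var(out$signals[, ch]), var(sig[, ch]) * (1 + 1e-8))
  }
  twice <- remove_eog_artifacts(out, threshold = 0.8)
  expect_equal(twice$signals, out$signals, tolerance = 1e-2)
  # a record with no ocular contamination passes through unchanged
  clean <- eeg_recording(cbind(C3 = rnorm(n), C4 = rnorm(n),
                               EOG1 = rnorm(n)), 100)
  kept <- remove_eog_artifacts(clean, threshold = 0.8)
  expect_equal(kept$signals, clean$signals, tolerance = 1e-8)
  expect_error(remove_eog_artifacts(eeg_recording(
    cbind(C3 = rnorm(50), EOG1 = rnorm(50)), 100)), "EEG")
})

test_that("epoching partitions the record and drops the trailing remainder", {
  rec <- make_rec(61 * 100, 100)
  ep <- epoch_record(rec, "Pz-Oz")
  expect_equal(dim(ep), c(2, 3000))
  expect_equal(as.numeric(t(ep)), rec$signals[1:6000, 1])
  expect_error(epoch_record(make_rec(100, 100), "Pz-Oz"), "shorter")
})
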