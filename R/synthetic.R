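# Synthetic polysomnography: a semi-Markov bout model generates ground-truth
# hypnograms; stage-conditioned mixtures of band-limited noise plus transient
# waveforms (spindles, K-complexes, slow eye movements) generate EEG/EOG.

#' Sleep-architecture generator parameters
#'
#' Stage dynamics are a semi-Markov bout model: a stage dwells for
#' `1 + Poisson(dwell - 1)` epochs and then jumps according to the embedded
#' transition matrix (no self-transitions). The night starts with a wake/N1
#' run realizing the sampled sleep onset latency, followed by the first N2
#' epoch (sleep onset per the AASM convention used here).
#'
#' @param dwell Named numeric vector of mean bout lengths in epochs for
#'   `N0, N1, N2, N3, REM` (all > 0).
#' @param transition 5x5 matrix of non-negative stage-to-stage weights
#'   (rows/cols in `stage_levels()` order). Rows are normalized to sum to 1;
#'   a row that cannot be normalized is a configuration error. The diagonal
#'   must be zero (dwell times carry the persistence).
#' @param sol_mean,sol_sd Sleep-onset-latency distribution (minutes, >= 0;
#'   truncated normal).
#' @param tsc_hours Total EEG collection time in hours (default 9, lights off
#'   at record start); the generated hypnogram has exactly
#'   `tsc_hours * 120` epochs.
#' @param n_cycles Nominal number of sleep cycles the dwell means imply
#'   (integer >= 1; descriptive, used for validation only).
#' @return An `architecture_params` list.
#' @export
architecture_params <- function(dwell = c(N0 = 2, N1 = 4, N2 = 20,
                                          N3 = 16, REM = 14),
                                transition = NULL,
                                sol_mean = 26, sol_sd = 6,
                                tsc_hours = 9, n_cycles = 4) {
  if (is.null(transition)) {
    transition <- matrix(0, 5, 5, dimnames = list(STAGE_LEVELS,
                                                  STAGE_LEVELS))
    transition["N0", ] <- c(0, 0.70, 0.30, 0, 0)
    transition["N1", ] <- c(0.05, 0, 0.90, 0, 0.05)
    transition["N2", ] <- c(0.05, 0.05, 0, 0.55, 0.35)
    transition["N3", ] <- c(0, 0, 0.75, 0, 0.25)
    transition["REM", ] <- c(0.10, 0.30, 0.60, 0, 0)
  }
  dwell <- dwell[STAGE_LEVELS]
  if (any(is.na(dwell)) || any(dwell <= 0))
    stop("`dwell` needs a positive mean bout length for every stage",
         call. = FALSE)
  if (any(transition < 0) || any(diag(transition) != 0))
    stop("transition weights must be non-negative with zero diagonal",
         call. = FALSE)
  rs <- rowSums(transition)
  if (any(rs <= 0))
    stop("transition weight rows must be normalizable (positive row sums)",
         call. = FALSE)
  transition <- transition / rs
  if (sol_mean < 0 || sol_sd < 0 || tsc_hours <= 0)
    stop("sol_mean, sol_sd >= 0 and tsc_hours > 0 required", call. = FALSE)
  if (n_cycles < 1 || n_cycles != round(n_cycles))
    stop("`n_cycles` must be an integer >= 1", call. = FALSE)
  structure(list(dwell = dwell, transition = transition,
                 sol_mean = sol_mean, sol_sd = sol_sd,
                 tsc_hours = tsc_hours, n_cycles = n_cycles),
            class = "architecture_params")
}

#' Expected stage composition of the bout model
#'
#' Closed form from the embedded chain: with stationary distribution
#' \eqn{\pi} of the transition matrix and mean dwells \eqn{d_s}, the expected
#' long-run fraction of epochs in stage \eqn{s} is
#' \eqn{\pi_s d_s / \sum_u \pi_u d_u}. Sleep-stage percentages (of total
#' sleep time) renormalize over the non-wake stages.
#'
#' @param params An [architecture_params()].
#' @return List with `epoch_fraction` (all five stages) and `sleep_pct`
#'   (N1/N2/N3/REM as % of sleep epochs).
#' @export
expected_stage_fractions <- function(params) {
  P <- params$transition
  ev <- eigen(t(P))
  i <- which.min(abs(ev$values - 1))
  pi_ <- Re(ev$vectors[, i]); pi_ <- pi_ / sum(pi_)
  w <- pi_ * params$dwell
  frac <- w / sum(w)
  names(frac) <- STAGE_LEVELS
  sleep <- frac[c("N1", "N2", "N3", "REM")]
  list(epoch_fraction = frac, sleep_pct = 100 * sleep / sum(sleep))
}

#' Calibrate the N3 dwell to a target N3 percentage
#'
#' Solves, in closed form, for the N3 mean bout length that makes the
#' expected realized N3% (of total sleep time) of a generated night equal
#' `target_pct`, holding everything else fixed. The solution accounts for
#' the finite-night structure: the pre-onset N1 run (which adds sleep
#' epochs containing no N3) and the wake fraction of the post-onset
#' semi-Markov section.
#'
#' @param params An [architecture_params()].
#' @param target_pct Target N3% of TST (0-100).
#' @return The modified `architecture_params`.
#' @export
calibrate_n3_dwell <- function(params, target_pct) {
  stopifnot(target_pct > 0, target_pct < 100)
  P <- params$transition
  ev <- eigen(t(P))
  i <- which.min(abs(ev$values - 1))
  pi_ <- Re(ev$vectors[, i]); pi_ <- pi_ / sum(pi_)
  names(pi_) <- STAGE_LEVELS
  # epoch weights A_s = pi_s * dwell_s; realized N3% solves
  #   q = A3 * T / ( (R + A3) * T + pre1 * (A0 + R + A3))
  # with T the post-onset epochs, pre1 the pre-onset N1 epochs,
  # R the weight of the other sleep stages.
  A <- pi_ * params$dwell
  sol_ep <- 2 * params$sol_mean
  pre1 <- 0.3 * sol_ep
  T_post <- round(params$tsc_hours * 120) - sol_ep
  R <- sum(A[c("N1", "N2", "REM")])
  q <- target_pct / 100
  d3 <- q * (R * T_post + pre1 * (A[["N0"]] + R)) /
    (T_post * (1 - q) - q * pre1) / pi_[["N3"]]
  if (d3 <= 0) stop("target N3% not attainable", call. = FALSE)
  params$dwell[["N3"]] <- unname(d3)
  params
}

#' Group effect realizing a target N3-percentage shift
#'
#' Converts a desired shift of the expected N3% (percentage points of TST)
#' into the equivalent N3 mean-bout shift via [calibrate_n3_dwell()], and
#' bundles it with a sleep-onset-latency shift into a [group_effect()].
#'
#' @param base The sham-group [architecture_params()].
#' @param delta_n3_pct Target N3% shift in percentage points.
#' @param delta_sol SOL mean shift in minutes (default 0).
#' @return A [group_effect()].
#' @export
effect_for_n3_shift <- function(base, delta_n3_pct, delta_sol = 0) {
  base_pct <- realized_n3_pct(base)
  shifted <- calibrate_n3_dwell(base, base_pct + delta_n3_pct)
  group_effect(delta_n3_dwell = shifted$dwell[["N3"]] - base$dwell[["N3"]],
               delta_sol = delta_sol)
}

# expected realized N3% of a night under `params` (inverse of the
# calibration formula)
realized_n3_pct <- function(params) {
  P <- params$transition
  ev <- eigen(t(P))
  i <- which.min(abs(ev$values - 1))
  pi_ <- Re(ev$vectors[, i]); pi_ <- pi_ / sum(pi_)
  names(pi_) <- STAGE_LEVELS
  A <- pi_ * params$dwell
  sol_ep <- 2 * params$sol_mean
  pre1 <- 0.3 * sol_ep
  T_post <- round(params$tsc_hours * 120) - sol_ep
  R <- sum(A[c("N1", "N2", "REM")])
  100 * A[["N3"]] * T_post /
    ((R + A[["N3"]]) * T_post + pre1 * sum(A))
}

#' Simulate a ground-truth hypnogram
#'
#' @param params An [architecture_params()].
#' @param seed Optional integer seed (sets R's RNG).
#' @return A [hypnogram()] of exactly `tsc_hours * 120` epochs. The first N2
#'   epoch falls at the sampled sleep onset latency; before it the subject is
#'   awake (N0) then drowsy (N1).
#' @export
simulate_hypnogram <- function(params, seed = NULL) {
  stopifnot(inherits(params, "architecture_params"))
  if (!is.null(seed)) set.seed(seed)
  n_ep <- round(params$tsc_hours * 120)
  sol_min <- max(0, rnorm(1, params$sol_mean, params$sol_sd))
  sol_ep <- min(round(2 * sol_min), max(0, n_ep - 2))
  n1_run <- min(sol_ep, max(1, round(0.3 * sol_ep)))
  if (sol_ep == 0) n1_run <- 0
  stages <- c(rep("N0", sol_ep - n1_run), rep("N1", n1_run))
  s <- "N2"
  while (length(stages) < n_ep) {
    d <- 1 + rpois(1, max(0, params$dwell[[s]] - 1))
    stages <- c(stages, rep(s, d))
    s <- sample(STAGE_LEVELS, 1, prob = params$transition[s, ])
  }
  hypnogram(stages[seq_len(n_ep)])
}

#' Stage-conditioned spectral template for EEG synthesis
#'
#' Encodes AASM-style stage signatures: alpha-dominant wake, mixed-theta N1
#' and REM (REM lower amplitude, more beta), theta/spindle N2 with K
#' complexes, delta-dominant high-amplitude N3. Weights are relative band
#' SDs over \{sub-delta 0-1.5, delta 1.5-4, theta 4-8, alpha 8-13, beta
#' 13-25, gamma 25-40 Hz\}; each stage has a unique dominant band.
#'
#' @param amplitude Named per-stage RMS amplitude in microvolts.
#' @param spindle_rate Spindles per minute in N2 epochs.
#' @param kcomplex_rate K-complexes per minute in N2 epochs.
#' @param sem_rate Slow-eye-movement bursts per minute on EOG channels during
#'   N0/N1/REM.
#' @param noise_floor Broadband noise floor SD in microvolts.
#' @return A `spectral_template` list.
#' @export
spectral_template <- function(amplitude = c(N0 = 40, N1 = 30, N2 = 45,
                                            N3 = 75, REM = 25),
                              spindle_rate = 3, kcomplex_rate = 1.5,
                              sem_rate = 4, noise_floor = 2) {
  weights <- rbind(
    #        sub_delta delta theta alpha beta gamma
    N0  = c(0.20, 0.30, 0.40, 1.00, 0.35, 0.15),
    N1  = c(0.25, 0.45, 1.00, 0.45, 0.25, 0.10),
    N2  = c(0.30, 0.60, 1.00, 0.40, 0.50, 0.10),
    N3  = c(0.50, 1.00, 0.45, 0.25, 0.15, 0.05),
    REM = c(0.15, 0.35, 1.00, 0.40, 0.55, 0.12))
  colnames(weights) <- c("sub_delta", "delta", "theta", "alpha", "beta",
                         "gamma")
  stopifnot(all(weights >= 0), all(amplitude[STAGE_LEVELS] > 0))
  structure(list(weights = weights, amplitude = amplitude[STAGE_LEVELS],
                 spindle_rate = spindle_rate,
                 kcomplex_rate = kcomplex_rate,
                 sem_rate = sem_rate, noise_floor = noise_floor,
                 bands = list(sub_delta = c(0.2, 1.5), delta = c(1.5, 4),
                              theta = c(4, 8), alpha = c(8, 13),
                              beta = c(13, 25), gamma = c(25, 40))),
            class = "spectral_template")
}

# one band-limited unit-SD noise track of n samples
band_noise <- function(n, edges, rate) {
  nyq <- rate / 2
  lo <- max(edges[1], 0.05) / nyq
  hi <- min(edges[2], nyq * 0.98) / nyq
  bf <- signal::butter(2, c(lo, hi), type = "pass")
  x <- signal::filtfilt(bf, rnorm(n + 2 * rate))
  x <- x[(rate + 1):(rate + n)]           # drop filter edges
  x / max(sd(x), 1e-12)
}

# smooth per-sample envelope from per-epoch values (1-s moving average)
epoch_envelope <- function(per_epoch, samples_per_epoch, rate) {
  env <- rep(per_epoch, each = samples_per_epoch)
  k <- rate                                 # 1-s crossfade
  kern <- rep(1 / k, k)
  sm <- stats::filter(env, kern, sides = 2)
  sm[is.na(sm)] <- env[is.na(sm)]
  as.numeric(sm)
}

gauss_burst <- function(n_samp, rate, t0, freq, width, amp, phase = 0) {
  t <- seq_len(n_samp) / rate
  amp * sin(2 * pi * freq * (t - t0) + phase) * exp(-((t - t0) / width)^2)
}

#' Synthesize multi-channel EEG from a hypnogram
#'
#' Each EEG channel is a sum of six band-limited noise tracks whose
#' per-epoch weights follow the stage's spectral template (with a 1-s
#' crossfade at epoch boundaries, so there are no amplitude discontinuities
#' beyond the noise scale), plus stage-specific transient waveforms: 13-Hz
#' spindle bursts and biphasic K-complexes in N2. Two EOG channels carry
#' low-frequency noise with slow-eye-movement bursts during wake/N1/REM.
#'
#' @param hyp A [hypnogram()].
#' @param template A [spectral_template()].
#' @param rate Sampling rate in Hz (>= 100).
#' @param channels EEG channel labels to synthesize (default `"Pz-Oz"`).
#' @param seed Optional integer seed.
#' @param subject_id,group Metadata forwarded to [eeg_recording()].
#' @return An [eeg_recording()] with the requested EEG channels plus
#'   `EOG1`, `EOG2`.
#' @export
synthesize_eeg <- function(hyp, template = spectral_template(), rate = 100,
                           channels = "Pz-Oz", seed = NULL,
                           subject_id = "s01", group = "unknown") {
  stopifnot(inherits(hyp, "hypnogram"), length(hyp) >= 1)
  if (rate < 100) stop("`rate` must be >= 100 Hz", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  spe <- round(epoch_sec(hyp) * rate)
  n <- length(hyp) * spe
  stages <- unclass(hyp)
  # per-epoch band SD targets: weight row scaled to the stage RMS amplitude
  W <- template$weights[stages, , drop = FALSE]
  amp <- template$amplitude[stages]
  W <- W / sqrt(rowSums(W^2)) * amp
  sig_list <- lapply(channels, function(ch) {
    x <- numeric(n)
    for (b in seq_along(template$bands)) {
      env <- epoch_envelope(W[, b], spe, rate)
      x <- x + band_noise(n, template$bands[[b]], rate) * env
    }
    x <- x + rnorm(n, sd = template$noise_floor)
    # N2 transients
    n2_ep <- which(stages == "N2")
    for (e in n2_ep) {
      nsp <- rpois(1, template$spindle_rate / 2)   # per 30-s epoch
      nkc <- rpois(1, template$kcomplex_rate / 2)
      if (nsp > 0) for (t0 in runif(nsp, 1, 29)) {
        idx <- ((e - 1) * spe + 1):(e * spe)
        x[idx] <- x[idx] + gauss_burst(spe, rate, t0, 13, 0.4, 12)
      }
      if (nkc > 0) for (t0 in runif(nkc, 1, 29)) {
        idx <- ((e - 1) * spe + 1):(e * spe)
        t <- seq_len(spe) / rate
        kc <- -45 * exp(-((t - t0) / 0.18)^2) +
          30 * exp(-((t - t0 - 0.35) / 0.22)^2)
        x[idx] <- x[idx] + kc
      }
    }
    x
  })
  # EOG channels: low-frequency noise + slow eye movements
  eog <- lapply(1:2, function(i) {
    y <- band_noise(n, c(0.2, 5), rate) * 10 + rnorm(n, sd = 2)
    sem_ep <- which(stages %in% c("N0", "N1", "REM"))
    for (e in sem_ep) {
      nsem <- rpois(1, template$sem_rate / 2)
      if (nsem > 0) for (t0 in runif(nsem, 2, 28)) {
        idx <- ((e - 1) * spe + 1):(e * spe)
        y[idx] <- y[idx] +
          gauss_burst(spe, rate, t0, 0.4, 1.2, 80, phase = (i - 1) * pi)
      }
    }
    y
  })
  sig <- do.call(cbind, c(sig_list, eog))
  colnames(sig) <- c(channels, "EOG1", "EOG2")
  eeg_recording(sig, rate, subject_id = subject_id, group = group)
}

#' Two-group exposure effect on the generative parameters
#'
#' Additive shifts applied to the exposed group's generator: longer/shorter
#' N3 and N2 mean bouts (epochs), a sleep-onset-latency shift (minutes), and
#' a sleep-efficiency target shift (percentage points, implemented as a
#' calibrated shrink of the non-sleep time: both the SOL mean and the wake
#' dwell are scaled by the factor that removes `delta_se`% of TSC from the
#' expected non-sleep time).
#'
#' @param delta_n3_dwell,delta_n2_dwell Mean-bout shifts in epochs.
#' @param delta_sol SOL mean shift in minutes.
#' @param delta_se Sleep-efficiency target shift in percentage points.
#' @return A `group_effect` list.
#' @export
group_effect <- function(delta_n3_dwell = 0, delta_n2_dwell = 0,
                         delta_sol = 0, delta_se = 0) {
  structure(list(delta_n3_dwell = delta_n3_dwell,
                 delta_n2_dwell = delta_n2_dwell,
                 delta_sol = delta_sol, delta_se = delta_se),
            class = "group_effect")
}

#' Apply a group effect to architecture parameters
#'
#' @param params An [architecture_params()].
#' @param effect A [group_effect()].
#' @return Shifted `architecture_params`; shifts that would leave a
#'   parameter's valid domain are an error.
#' @export
apply_group_effect <- function(params, effect) {
  p <- params
  p$dwell[["N3"]] <- p$dwell[["N3"]] + effect$delta_n3_dwell
  p$dwell[["N2"]] <- p$dwell[["N2"]] + effect$delta_n2_dwell
  p$sol_mean <- p$sol_mean + effect$delta_sol
  if (any(p$dwell <= 0) || p$sol_mean < 0)
    stop("group effect pushes a parameter out of its valid domain",
         call. = FALSE)
  if (effect$delta_se != 0) {
    frac <- expected_stage_fractions(params)$epoch_fraction
    tsc_min <- params$tsc_hours * 60
    wake_min <- frac[["N0"]] * (tsc_min - params$sol_mean)
    nonsleep <- params$sol_mean + wake_min
    f <- max(0.05, 1 - (effect$delta_se / 100 * tsc_min) / nonsleep)
    p$sol_mean <- p$sol_mean * f
    p$dwell[["N0"]] <- max(0.25, p$dwell[["N0"]] * f)
  }
  p
}

#' Simulate a two-group cohort of nights
#'
#' Generates `n_exposed + n_sham` subjects, the exposed group from
#' `apply_group_effect(base, effect)`, each night with a subject seed derived
#' reproducibly from `seed`. Cohort sizes default to 21 exposed vs 20 sham.
#'
#' @param n_exposed,n_sham Group sizes (>= 2).
#' @param base An [architecture_params()].
#' @param effect A [group_effect()].
#' @param seed Master seed.
#' @param with_eeg Also synthesize EEG for each night (slower); otherwise
#'   only ground-truth hypnograms are produced.
#' @param template,rate,channels Passed to [synthesize_eeg()] when
#'   `with_eeg = TRUE`.
#' @return A list of class `psg_cohort`; each element has `subject_id`,
#'   `group`, `seed`, `hypnogram` and (optionally) `recording`.
#' @export
simulate_cohort <- function(n_exposed = 21, n_sham = 20,
                            base = architecture_params(),
                            effect = group_effect(), seed = 1,
                            with_eeg = FALSE,
                            template = spectral_template(), rate = 100,
                            channels = "Pz-Oz") {
  if (n_exposed < 2 || n_sham < 2)
    stop("need at least 2 subjects per group", call. = FALSE)
  exposed_params <- apply_group_effect(base, effect)
  groups <- c(rep("exposed", n_exposed), rep("sham", n_sham))
  out <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    par_i <- if (groups[i] == "exposed") exposed_params else base
    seed_i <- as.integer((as.numeric(seed) * 10007 + i * 7919) %%
                           2147483647)
    hyp <- simulate_hypnogram(par_i, seed = seed_i)
    subj <- sprintf("%s%02d", ifelse(groups[i] == "exposed", "e", "s"),
                    if (groups[i] == "exposed") i else i - n_exposed)
    rec <- NULL
    if (with_eeg)
      rec <- synthesize_eeg(hyp, template, rate, channels,
                            seed = seed_i + 1L, subject_id = subj,
                            group = groups[i])
    out[[i]] <- list(subject_id = subj, group = groups[i], seed = seed_i,
                     hypnogram = hyp, recording = rec)
  }
  structure(out, class = "psg_cohort", master_seed = seed)
}

#' Write a cohort manifest CSV
#'
#' One row per subject: `subject_id`, `group`, `seed`, and the hypnogram
#' file written next to the manifest.
#'
#' @param cohort A `psg_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if absent).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort, function(s) {
    hpath <- file.path(dir, paste0(s$subject_id, "_hypnogram.csv"))
    write_hypnogram(s$hypnogram, hpath)
    data.frame(subject_id = s$subject_id, group = s$group, seed = s$seed,
               hypnogram = basename(hpath))
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.csv")
  write.csv(manifest, mpath, row.names = FALSE, quote = FALSE)
  invisible(mpath)
}
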