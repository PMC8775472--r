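# Per-epoch feature extraction: 8 time-domain statistics, 9 spectral
# features from a Welch PSD, and 3 entropy measures, in a fixed 20-name
# order.

FEATURE_NAMES <- c("MINV", "MAXV", "AMV", "MNV", "SD", "V", "S", "K",
                   "fc", "fsigma", "pfc",
                   "gamma", "beta", "alpha", "theta", "delta", "Kc",
                   "FUEN", "SampEN", "MSES")

#' Names of the 20 per-epoch features, in canonical order
#' @return Character vector of length 20.
#' @export
feature_names <- function() FEATURE_NAMES

#' Feature-extraction configuration
#'
#' @param seg_sec Welch segment length in seconds (default 4, i.e. 0.25 Hz
#'   resolution at 100 Hz).
#' @param overlap Welch segment overlap fraction (default 0.5).
#' @param band_edges Named list of `c(low, high)` band edges in Hz. Defaults:
#'   Kc 0-1.5 (sub-delta, the K-complex band), delta 1.5-4, theta 4-8,
#'   alpha 8-13, beta 13-25, gamma 25-40.
#' @param band_mode `"density"` (mean PSD over the band, the default) or
#'   `"power"` (integrated band power).
#' @param moment_norm `"n-1"` (skewness/kurtosis normalized by 1/(N-1), the
#'   default) or `"n"` (conventional 1/N estimator).
#' @param fuen,sampen,mses Parameter lists for the three entropy features:
#'   `fuen` has `m`, `n` and `r_mult` (r = r_mult * SD of the epoch; defaults
#'   m = 2, n = 2, r_mult = 0.3); `sampen` has `m`, `r_mult` (defaults 2,
#'   0.2); `mses` has `tau`, `m`, `r_mult` (defaults 11, 2, 0.15, with r
#'   anchored to the original-series SD).
#' @return A `feature_config` list.
#' @export
feature_config <- function(seg_sec = 4, overlap = 0.5,
                           band_edges = NULL,
                           band_mode = c("density", "power"),
                           moment_norm = c("n-1", "n"),
                           fuen = list(m = 2, n = 2, r_mult = 0.3),
                           sampen = list(m = 2, r_mult = 0.2),
                           mses = list(tau = 11, m = 2, r_mult = 0.15)) {
  if (is.null(band_edges))
    band_edges <- list(Kc = c(0, 1.5), delta = c(1.5, 4), theta = c(4, 8),
                       alpha = c(8, 13), beta = c(13, 25), gamma = c(25, 40))
  edges <- unlist(band_edges)
  if (any(vapply(band_edges, function(e) e[2] <= e[1], logical(1))))
    stop("band edges must be increasing", call. = FALSE)
  stopifnot(fuen$r_mult > 0, sampen$r_mult > 0, mses$r_mult > 0,
            mses$tau >= 1, fuen$m >= 1, sampen$m >= 1, mses$m >= 1)
  structure(list(seg_sec = seg_sec, overlap = overlap,
                 band_edges = band_edges,
                 band_mode = match.arg(band_mode),
                 moment_norm = match.arg(moment_norm),
                 fuen = fuen, sampen = sampen, mses = mses),
            class = "feature_config")
}

#' Welch power spectral density
#'
#' Averaged modified periodogram: Hann-windowed segments of `seg_sec`
#' seconds with fractional `overlap`, one-sided density scaling
#' (units^2 / Hz).
#'
#' @param x Numeric vector.
#' @param rate Sampling rate in Hz.
#' @param seg_sec Segment length in seconds.
#' @param overlap Overlap fraction in `[0, 1)`.
#' @return A list with `freq` (Hz) and `psd`.
#' @export
welch_psd <- function(x, rate, seg_sec = 4, overlap = 0.5) {
  L <- round(seg_sec * rate)
  if (length(x) < L) L <- length(x)
  step <- max(1, round(L * (1 - overlap)))
  starts <- seq(1, length(x) - L + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / (L + 1)) # Hann
  scale <- rate * sum(w^2)
  nf <- floor(L / 2) + 1
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + L - 1)] * w
    P <- abs(fft(seg))^2 / scale
    acc <- acc + P[seq_len(nf)]
  }
  psd <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist when L is even)
  dbl <- rep(2, nf); dbl[1] <- 1
  if (L %% 2 == 0) dbl[nf] <- 1
  list(freq = (seq_len(nf) - 1) * rate / L, psd = psd * dbl)
}

#' Time-domain features of one epoch
#'
#' Minimum, maximum, mean, median, standard deviation, variance, skewness and
#' kurtosis. The median follows the sorted-sequence definition (even N: mean
#' of the two central order statistics). Skewness and kurtosis are
#' \eqn{\frac{1}{N-1}\sum((x-\bar x)/SD)^{3,4}} by default (`moment_norm =
#' "n-1"`); a constant epoch (SD = 0) yields S = K = 0 with a
#' `"degenerate"` attribute flag.
#'
#' @param x Numeric vector (length >= 4).
#' @param moment_norm `"n-1"` or `"n"`.
#' @return Named numeric vector `MINV, MAXV, AMV, MNV, SD, V, S, K`.
#' @export
time_domain_features <- function(x, moment_norm = c("n-1", "n")) {
  moment_norm <- match.arg(moment_norm)
  N <- length(x)
  if (N < 4) stop("need at least 4 samples", call. = FALSE)
  amv <- mean(x)
  s_d <- sd(x)
  denom <- if (moment_norm == "n-1") N - 1 else N
  degenerate <- s_d == 0
  if (degenerate) {
    S <- 0; K <- 0
  } else {
    z <- (x - amv) / s_d
    S <- sum(z^3) / denom
    K <- sum(z^4) / denom
  }
  out <- c(MINV = min(x), MAXV = max(x), AMV = amv, MNV = median(x),
           SD = s_d, V = s_d^2, S = S, K = K)
  attr(out, "degenerate") <- degenerate
  out
}

#' Spectral features of one epoch
#'
#' From the Welch PSD restricted to 0-40 Hz: the power-weighted spectral
#' centroid `fc`, the power-weighted spectral spread `fsigma`, the PSD
#' interpolated at the centroid `pfc`, and one value per rhythm band
#' (`gamma`, `beta`, `alpha`, `theta`, `delta`, `Kc`), each the mean PSD
#' (density) over the band by default. An all-zero epoch returns zeros with a
#' `"degenerate"` flag.
#'
#' @param x Numeric vector (one 30-s epoch, band-limited 0.5-40 Hz).
#' @param rate Sampling rate in Hz.
#' @param cfg A [feature_config()].
#' @return Named numeric vector
#'   `fc, fsigma, pfc, gamma, beta, alpha, theta, delta, Kc`.
#' @export
spectral_features <- function(x, rate, cfg = feature_config()) {
  ps <- welch_psd(x, rate, cfg$seg_sec, cfg$overlap)
  keep <- ps$freq <= 40
  f <- ps$freq[keep]; p <- ps$psd[keep]
  tot <- sum(p)
  if (tot <= 0) {
    out <- setNames(numeric(9), c("fc", "fsigma", "pfc",
                                  "gamma", "beta", "alpha", "theta",
                                  "delta", "Kc"))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  fc <- sum(f * p) / tot
  fsigma <- sqrt(sum(p * (f - fc)^2) / tot)
  pfc <- approx(f, p, xout = fc, rule = 2)$y
  df <- f[2] - f[1]
  band_val <- vapply(cfg$band_edges, function(e) {
    in_band <- f >= e[1] & f < e[2]
    if (!any(in_band)) return(0)
    if (cfg$band_mode == "density") mean(p[in_band])
    else sum(p[in_band]) * df
  }, numeric(1))
  out <- c(fc = fc, fsigma = fsigma, pfc = pfc,
           gamma = band_val[["gamma"]], beta = band_val[["beta"]],
           alpha = band_val[["alpha"]], theta = band_val[["theta"]],
           delta = band_val[["delta"]], Kc = band_val[["Kc"]])
  attr(out, "degenerate") <- FALSE
  out
}

#' The full 20-feature vector of one epoch
#'
#' Concatenates [time_domain_features()], [spectral_features()] and the three
#' entropy features ([fuzzy_entropy()] with r = 0.3 SD, [sample_entropy()]
#' with r = 0.2 SD, [multiscale_entropy()] at scale 11 with r = 0.15 SD by
#' default) in the fixed [feature_names()] order.
#'
#' @param x Numeric vector (one epoch).
#' @param rate Sampling rate in Hz.
#' @param cfg A [feature_config()].
#' @return Named numeric vector of length 20. A `"degenerate"` attribute
#'   flags constant/all-zero epochs.
#' @export
feature_vector <- function(x, rate, cfg = feature_config()) {
  td <- time_domain_features(x, cfg$moment_norm)
  sp <- spectral_features(x, rate, cfg)
  s_d <- td[["SD"]]
  if (s_d > 0) {
    fuen <- fuzzy_entropy(x, m = cfg$fuen$m, n = cfg$fuen$n,
                          r = cfg$fuen$r_mult * s_d)
    samp <- sample_entropy(x, m = cfg$sampen$m, r = cfg$sampen$r_mult * s_d)
    mses <- multiscale_entropy(x, tau = cfg$mses$tau, m = cfg$mses$m,
                               r = cfg$mses$r_mult * s_d)
  } else {
    fuen <- 0; samp <- 0; mses <- 0
  }
  out <- c(td, sp, FUEN = fuen, SampEN = samp, MSES = mses)[FEATURE_NAMES]
  attr(out, "degenerate") <- isTRUE(attr(td, "degenerate")) ||
    isTRUE(attr(sp, "degenerate"))
  out
}

#' Extract the feature matrix of a recording channel
#'
#' Epochs `channel` into 30-s windows and computes the 20-feature vector for
#' each.
#'
#' @param rec A preprocessed [eeg_recording()].
#' @param channel Channel label.
#' @param cfg A [feature_config()].
#' @param stages Optional [hypnogram()] (or character vector) of per-epoch
#'   stage labels to attach.
#' @return A data.frame with `epoch_index` (0-based), the 20 feature columns,
#'   `subject_id`, and `stage` when labels were given.
#' @export
extract_features <- function(rec, channel, cfg = feature_config(),
                             stages = NULL) {
  ep <- epoch_record(rec, channel)
  fm <- t(apply(ep, 1, feature_vector, rate = attr(ep, "rate"), cfg = cfg))
  colnames(fm) <- FEATURE_NAMES
  out <- data.frame(epoch_index = seq_len(nrow(fm)) - 1L, fm,
                    check.names = FALSE)
  out$subject_id <- rec$subject_id
  if (!is.null(stages)) {
    stages <- as.character(stages)
    if (length(stages) < nrow(fm))
      stop("fewer stage labels than epochs", call. = FALSE)
    out$stage <- stages[seq_len(nrow(fm))]
  }
  out
}
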