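# Independent brute-force oracles, deliberately naive: plain double loops
# over the printed definitions. They never share code with the package
# implementations they check.

naive_sample_entropy <- function(x, m, r) {
  N <- length(x)
  nt <- N - m
  A <- 0L; B <- 0L
  for (i in seq_len(nt - 1)) {
    for (j in (i + 1):nt) {
      dm <- max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))
      if (dm <= r) {
        B <- B + 1L
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1L
      }
    }
  }
  if (A == 0L || B == 0L) return(-log(2 / ((N - m - 1) * (N - m))))
  -log(A / B)
}

naive_fuzzy_phi <- function(x, m, n, r) {
  N <- length(x)
  nt <- N - m
  u <- matrix(0, nt, m)
  for (i in seq_len(nt)) u[i, ] <- x[i:(i + m - 1)] - mean(x[i:(i + m - 1)])
  s <- 0
  for (i in seq_len(nt - 1)) {
    for (j in (i + 1):nt) {
      d <- max(abs(u[i, ] - u[j, ]))
      s <- s + exp(-d^n / r)
    }
  }
  2 * s / (nt * (nt - 1))
}

naive_fuzzy_entropy <- function(x, m, n, r) {
  log(naive_fuzzy_phi(x, m, n, r)) - log(naive_fuzzy_phi(x, m + 1, n, r))
}

naive_multiscale_entropy <- function(x, tau, m, r) {
  nb <- floor(length(x) / tau)
  y <- numeric(nb)
  for (b in seq_len(nb)) y[b] <- mean(x[((b - 1) * tau + 1):(b * tau)])
  naive_sample_entropy(y, m, r)
}

# direct (single, unwindowed) periodogram band power, one-sided
oracle_band_power <- function(x, rate, lo, hi) {
  N <- length(x)
  P <- abs(fft(x))^2 / (N * rate)
  f <- (seq_len(N) - 1) * rate / N
  keep <- f <= rate / 2
  P <- 2 * P[keep]; f <- f[keep]
  sum(P[f >= lo & f < hi]) * rate / N
}

# deterministic test hypnogram builder
hyp_of <- function(...) {
  runs <- list(...)
  hypnogram(unlist(lapply(runs, function(r) rep(r[[1]], r[[2]]))))
}
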