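# Nonlinear (entropy) features. The compiled kernels live in src/entropy.cpp;
# these wrappers validate inputs and fix conventions (absolute tolerance r,
# Chebyshev distance, self-matches excluded).

#' Sample entropy
#'
#' \eqn{-\ln(A/B)} where \eqn{B} counts template pairs of length `m` within
#' Chebyshev distance `r` and \eqn{A} those also matching at length `m + 1`;
#' both counts run over the \eqn{N - m} templates and self-matches are
#' excluded. When no length-`m + 1` match exists the finite-sample cap
#' \eqn{-\ln(2/((N-m-1)(N-m)))} is returned rather than infinity.
#'
#' @param x Numeric vector (length >= m + 2).
#' @param m Template length (default 2).
#' @param r Match tolerance, in the amplitude units of `x` (e.g. `0.2 * sd(x)`).
#' @return A single non-negative number.
#' @export
sample_entropy <- function(x, m = 2, r) {
  x <- as.numeric(x)
  if (length(x) < m + 2) stop("need length(x) >= m + 2", call. = FALSE)
  if (r < 0) stop("`r` must be >= 0", call. = FALSE)
  .sampen_cpp(x, as.integer(m), r)
}

#' Fuzzy entropy
#'
#' Sample-entropy variant with a soft match: templates of length `m` are
#' mean-centred and a pair at Chebyshev distance \eqn{d} contributes
#' membership \eqn{\exp(-d^n/r)}. The statistic is
#' \eqn{\ln\varphi_m - \ln\varphi_{m+1}} with \eqn{\varphi_k} the mean
#' membership over all pairs of length-`k` templates. Note that with
#' \eqn{n \neq 1} this membership is not amplitude-scale invariant even for
#' SD-proportional `r`; see the methods vignette.
#'
#' @inheritParams sample_entropy
#' @param n Fuzzy membership exponent (default 2).
#' @param r Membership width, amplitude units (e.g. `0.3 * sd(x)`), > 0.
#' @return A single number.
#' @export
fuzzy_entropy <- function(x, m = 2, n = 2, r) {
  x <- as.numeric(x)
  if (length(x) < m + 3) stop("need length(x) >= m + 3", call. = FALSE)
  if (r <= 0) stop("`r` must be > 0", call. = FALSE)
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  .fuzzyen_cpp(x, as.integer(m), as.numeric(n), r)
}

#' Multiscale (coarse-grained) sample entropy at a single scale
#'
#' Coarse-grains `x` by non-overlapping means of `tau` consecutive samples
#' (any remainder dropped), then computes [sample_entropy()] of the coarse
#' series with the same `m` and `r`. `r` is conventionally anchored to the
#' SD of the *original* series, so pass it precomputed (e.g.
#' `0.15 * sd(x)`). At `tau = 1` this is exactly the sample entropy of `x`.
#'
#' @inheritParams sample_entropy
#' @param tau Scale factor (block length), integer >= 1.
#' @return A single number.
#' @export
multiscale_entropy <- function(x, tau = 11, m = 2, r) {
  x <- as.numeric(x)
  tau <- as.integer(tau)
  if (tau < 1) stop("`tau` must be >= 1", call. = FALSE)
  if (length(x) < tau * (m + 2))
    stop("need length(x) >= tau * (m + 2)", call. = FALSE)
  y <- coarse_grain(x, tau)
  sample_entropy(y, m = m, r = r)
}

coarse_grain <- function(x, tau) {
  if (tau == 1) return(x)
  nb <- floor(length(x) / tau)
  colMeans(matrix(x[seq_len(nb * tau)], nrow = tau))
}
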