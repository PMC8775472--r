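# Two-group cohort statistics: t-tests, bootstrap CIs, relative changes and
# the per-metric comparison table.

#' Two-sample t-test
#'
#' Independent two-sample t-test on the difference `mean(a) - mean(b)`,
#' pooled-variance by default (Welch via `var_equal = FALSE`). Two identical
#' zero-variance samples return t = 0, p = 1 instead of an error.
#'
#' @param a,b Numeric samples (each n >= 2).
#' @param var_equal Pooled-variance (TRUE, default) or Welch (FALSE).
#' @param conf_level Confidence level for the CI (default 0.95).
#' @return List with `t`, `df`, `p`, `ci` (on mean(a) - mean(b)), and
#'   `estimate`.
#' @export
two_sample_t <- function(a, b, var_equal = TRUE, conf_level = 0.95) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (var(a) == 0 && var(b) == 0) {
    d <- mean(a) - mean(b)
    if (d == 0)
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1,
                  ci = c(0, 0), estimate = 0))
    return(list(t = sign(d) * Inf, df = length(a) + length(b) - 2, p = 0,
                ci = c(d, d), estimate = d))
  }
  tt <- t.test(a, b, var.equal = var_equal, conf.level = conf_level)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, ci = as.numeric(tt$conf.int),
       estimate = mean(a) - mean(b))
}

#' Paired t-test
#'
#' One-sample t-test on the paired differences `a - b`. A constant non-zero
#' difference (zero variance) returns a signed infinite t with p = 0 and a
#' `degenerate` flag.
#'
#' @param a,b Aligned numeric samples of equal length (n >= 2).
#' @return List with `t`, `df`, `p`, `estimate` (mean difference) and
#'   `degenerate`.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b))
    stop("paired samples must have equal length", call. = FALSE)
  stopifnot(length(a) >= 2)
  d <- a - b
  if (var(d) == 0) {
    if (mean(d) == 0)
      return(list(t = 0, df = length(d) - 1, p = 1, estimate = 0,
                  degenerate = TRUE))
    return(list(t = sign(mean(d)) * Inf, df = length(d) - 1, p = 0,
                estimate = mean(d), degenerate = TRUE))
  }
  tt <- t.test(d)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       estimate = mean(d), degenerate = FALSE)
}

#' Bootstrap percentile confidence interval for a two-group statistic
#'
#' Resamples with replacement within each group `B` times and returns the
#' percentile CI of `statistic(a*, b*)` (default: difference of means).
#'
#' @param a,b Numeric samples.
#' @param B Number of bootstrap samples (>= 100; default 1000).
#' @param statistic Function of two samples (default
#'   `mean(a) - mean(b)`).
#' @param conf_level Confidence level (default 0.95).
#' @param seed Integer seed for reproducibility.
#' @return Numeric `c(lower, upper)`.
#' @export
bootstrap_ci <- function(a, b, B = 1000,
                         statistic = function(a, b) mean(a) - mean(b),
                         conf_level = 0.95, seed = 1) {
  if (B < 100) stop("need B >= 100 bootstrap samples", call. = FALSE)
  set.seed(seed)
  stats_boot <- vapply(seq_len(B), function(i) {
    statistic(a[sample.int(length(a), replace = TRUE)],
              b[sample.int(length(b), replace = TRUE)])
  }, numeric(1))
  alpha <- 1 - conf_level
  unname(quantile(stats_boot, c(alpha / 2, 1 - alpha / 2), type = 7))
}

#' Relative change between group means (%)
#'
#' For a metric reported as a decrease under exposure,
#' `(sham - exposed) / sham * 100`; for an increase,
#' `(exposed - sham) / sham * 100`. The sham (reference) mean must be
#' non-zero.
#'
#' @param exposed_mean,sham_mean Group means.
#' @param direction `"decrease"` or `"increase"`.
#' @param digits Rounding for reporting (default 2 decimals).
#' @return Percent change (positive when the change goes in the stated
#'   direction).
#' @export
relative_change <- function(exposed_mean, sham_mean,
                            direction = c("decrease", "increase"),
                            digits = 2) {
  direction <- match.arg(direction)
  if (sham_mean == 0)
    stop("relative change undefined: reference mean is zero", call. = FALSE)
  delta <- if (direction == "decrease") sham_mean - exposed_mean
           else exposed_mean - sham_mean
  round(delta / sham_mean * 100, digits)
}

COMPARISON_METRICS <- c("N1_pct", "N2_pct", "N3_pct", "REM_pct", "SE",
                        "WN", "SOL", "RL")

#' Compare sleep metrics between two cohorts
#'
#' One row per metric: group means and SDs, the difference
#' (sham - exposed), its t-based 95% CI, bootstrap percentile CI, t and p
#' (two-sample, pooled variance by default) and a significance flag at
#' `alpha`. No multiple-testing correction by default; `adjust = "holm"`
#' applies a Holm correction to the flags and adjusted p-values.
#'
#' @param exposed,sham Metric data.frames from [cohort_metrics()] (or any
#'   data.frames containing the metric columns).
#' @param metrics Metric columns to compare.
#' @param var_equal Pooled-variance t (default) or Welch.
#' @param B Bootstrap samples for the percentile CI (default 1000).
#' @param seed Seed for the bootstrap.
#' @param alpha Significance level (default 0.05).
#' @param adjust `"none"` (default) or `"holm"`.
#' @return A `cohort_comparison` data.frame.
#' @export
compare_cohorts <- function(exposed, sham, metrics = COMPARISON_METRICS,
                            var_equal = TRUE, B = 1000, seed = 1,
                            alpha = 0.05, adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  metrics <- intersect(metrics, intersect(names(exposed), names(sham)))
  if (!length(metrics)) stop("no shared metric columns", call. = FALSE)
  rows <- lapply(seq_along(metrics), function(i) {
    m <- metrics[i]
    a <- exposed[[m]]; a <- a[is.finite(a)]
    b <- sham[[m]]; b <- b[is.finite(b)]
    if (length(a) < 2 || length(b) < 2) {
      warning("metric ", m, " has fewer than 2 finite values per group; ",
              "comparison skipped")
      return(data.frame(metric = m, exposed_mean = NA_real_,
                        exposed_sd = NA_real_, sham_mean = NA_real_,
                        sham_sd = NA_real_, difference = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        boot_ci_low = NA_real_, boot_ci_high = NA_real_,
                        t = NA_real_, p = NA_real_))
    }
    # difference convention: sham - exposed
    tt <- two_sample_t(b, a, var_equal = var_equal)
    bci <- bootstrap_ci(b, a, B = B, seed = seed + i)
    data.frame(metric = m,
               exposed_mean = mean(a), exposed_sd = sd(a),
               sham_mean = mean(b), sham_sd = sd(b),
               difference = mean(b) - mean(a),
               ci_low = tt$ci[1], ci_high = tt$ci[2],
               boot_ci_low = bci[1], boot_ci_high = bci[2],
               t = tt$t, p = tt$p)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- if (adjust == "holm") stats::p.adjust(out$p, "holm") else out$p
  out$significant <- out$p_adj < alpha
  class(out) <- c("cohort_comparison", "data.frame")
  attr(out, "alpha") <- alpha
  out
}

#' Format a cohort comparison like a published summary table
#'
#' Percentage-valued metrics (stage percentages and SE) are reported as
#' proportion differences (divided by 100, 3 decimals); SOL stays in
#' minutes, WN in counts, RL in hours.
#'
#' @param cmp A `cohort_comparison` from [compare_cohorts()].
#' @return A data.frame with formatted columns `exposed`, `sham`,
#'   `difference_fmt`, `t`, `p`.
#' @export
format_comparison_table <- function(cmp) {
  pct_metrics <- c("N1_pct", "N2_pct", "N3_pct", "REM_pct", "SE")
  fmt_diff <- ifelse(cmp$metric %in% pct_metrics,
                     sprintf("%.3f", cmp$difference / 100),
                     sprintf("%.2f", cmp$difference))
  data.frame(metric = cmp$metric,
             exposed = sprintf("%.2f ± %.1f", cmp$exposed_mean,
                               cmp$exposed_sd),
             sham = sprintf("%.2f ± %.1f", cmp$sham_mean, cmp$sham_sd),
             difference_fmt = fmt_diff,
             t = round(cmp$t, 2), p = signif(cmp$p, 3),
             significant = cmp$significant)
}
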