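# Sleep-architecture metrics from a scored hypnogram. Conventions: sleep
# onset = first N2 epoch; SOL is measured from lights-off; REM latency from
# the first N1; awakenings are interior maximal wake bouts between sleep
# onset and the last non-wake epoch.

stage_hours <- function(h, stage) {
  sum(unclass(h) %in% stage) * epoch_sec(h) / 3600
}

#' Total sleep time (hours)
#'
#' Sum of all non-wake (N1 + N2 + N3 + REM) epoch durations.
#'
#' @param h A [hypnogram()].
#' @return TST in hours.
#' @export
total_sleep_time <- function(h) {
  stage_hours(h, c("N1", "N2", "N3", "REM"))
}

#' Stage percentages of total sleep time
#'
#' @param h A [hypnogram()] with TST > 0.
#' @return Named vector `N1_pct, N2_pct, N3_pct, REM_pct` summing to 100.
#' @export
stage_percentages <- function(h) {
  tst <- total_sleep_time(h)
  if (tst <= 0) stop("stage percentages undefined: TST = 0", call. = FALSE)
  d <- vapply(c("N1", "N2", "N3", "REM"), function(s) stage_hours(h, s),
              numeric(1))
  setNames(100 * d / tst, c("N1_pct", "N2_pct", "N3_pct", "REM_pct"))
}

#' Sleep efficiency (%)
#'
#' `TST / TSC * 100`, where TSC is the total EEG collection time (9 h by
#' default). Accepts either a hypnogram (TST computed from it) or a numeric
#' TST in hours.
#'
#' @param x A [hypnogram()], or TST in hours.
#' @param tsc Total collection time in hours (> 0).
#' @return SE in percent, clamped to \[0, 100\] (with a warning if
#'   TST > TSC).
#' @export
sleep_efficiency <- function(x, tsc = 9) {
  stopifnot(tsc > 0)
  tst <- if (inherits(x, "hypnogram")) total_sleep_time(x) else as.numeric(x)
  se <- tst / tsc * 100
  if (se > 100) {
    warning("TST exceeds TSC; SE clamped to 100")
    se <- 100
  }
  max(0, se)
}

#' Sleep onset latency (minutes)
#'
#' Time from lights-off to the first N2 epoch.
#'
#' @param h A [hypnogram()] containing at least one N2 epoch.
#' @return SOL in minutes.
#' @export
sleep_onset_latency <- function(h) {
  first_n2 <- match("N2", unclass(h))
  if (is.na(first_n2))
    stop("SOL undefined: no N2 epoch in hypnogram", call. = FALSE)
  lo <- lights_off_epoch(h)
  if (first_n2 - 1L < lo)
    stop("first N2 precedes lights-off", call. = FALSE)
  (first_n2 - 1L - lo) * epoch_sec(h) / 60
}

#' REM latency
#'
#' Time from the first N1 epoch to the first REM epoch, in hours, plus
#' `RL% = RL / TST * 100`.
#'
#' @param h A [hypnogram()] with an N1 epoch preceding a REM epoch.
#' @return List with `RL` (hours) and `RL_pct`.
#' @export
rem_latency <- function(h) {
  s <- unclass(h)
  first_n1 <- match("N1", s)
  first_rem <- match("REM", s)
  if (is.na(first_n1) || is.na(first_rem) || first_rem <= first_n1)
    stop("REM latency undefined: need an N1 epoch before the first REM",
         call. = FALSE)
  rl <- (first_rem - first_n1) * epoch_sec(h) / 3600
  list(RL = rl, RL_pct = rl / total_sleep_time(h) * 100)
}

#' Awakening count
#'
#' Number of maximal contiguous wake (N0) runs strictly after sleep onset
#' (the first N2 epoch) and before the final non-wake epoch; leading wake
#' (sleep latency) and trailing wake are not awakenings.
#'
#' @param h A [hypnogram()].
#' @return Integer count (0 when there is no sleep onset, with a warning).
#' @export
awakening_count <- function(h) {
  s <- unclass(h)
  onset <- match("N2", s)
  if (is.na(onset)) {
    warning("no sleep onset (no N2 epoch); WN = 0")
    return(0L)
  }
  last_sleep <- max(which(s != "N0"))
  if (last_sleep <= onset) return(0L)
  interior <- s[onset:last_sleep]
  r <- rle(interior)
  sum(r$values == "N0")
}

#' All sleep metrics for one night
#'
#' @param h A [hypnogram()].
#' @param tsc Total collection time in hours.
#' @return A one-row data.frame: `TST` (h), `N1_pct..REM_pct`, `SE`, `SOL`
#'   (min), `RL` (h), `RL_pct`, `WN`, `TSC`. RL is `NA` when undefined.
#' @export
sleep_metrics <- function(h, tsc = 9) {
  na_pct <- setNames(rep(NA_real_, 4),
                     c("N1_pct", "N2_pct", "N3_pct", "REM_pct"))
  pct <- tryCatch(stage_percentages(h), error = function(e) {
    warning("stage percentages undefined for this night (TST = 0)")
    na_pct
  })
  rl <- tryCatch(rem_latency(h), error = function(e) list(RL = NA_real_,
                                                          RL_pct = NA_real_))
  sol <- tryCatch(sleep_onset_latency(h), error = function(e) {
    warning("SOL undefined for this night (no N2 epoch)")
    NA_real_
  })
  data.frame(TST = total_sleep_time(h),
             N1_pct = pct[["N1_pct"]], N2_pct = pct[["N2_pct"]],
             N3_pct = pct[["N3_pct"]], REM_pct = pct[["REM_pct"]],
             SE = sleep_efficiency(h, tsc),
             SOL = sol,
             RL = rl$RL, RL_pct = rl$RL_pct,
             WN = suppressWarnings(awakening_count(h)), TSC = tsc)
}

#' Per-night metrics table for a cohort
#'
#' @param cohort A `psg_cohort` from [simulate_cohort()], or a list of
#'   elements with `hypnogram`, `subject_id`, `group`.
#' @param tsc Total collection time in hours.
#' @return A data.frame, one row per night, with `subject_id` and `group`
#'   columns prepended.
#' @export
cohort_metrics <- function(cohort, tsc = 9) {
  rows <- lapply(cohort, function(s) {
    m <- sleep_metrics(s$hypnogram, tsc)
    cbind(data.frame(subject_id = s$subject_id, group = s$group), m)
  })
  do.call(rbind, rows)
}
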