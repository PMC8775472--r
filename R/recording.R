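#' Multi-channel EEG recording
#'
#' Container for a polysomnographic recording: a numeric matrix of samples
#' (rows) by channels (columns, named with 10-20 labels such as `"Pz-Oz"`,
#' `"C3"`, or `"EOG1"`), the sampling rate, the lights-off time and subject
#' metadata. Signals are in microvolts.
#'
#' @param signals Numeric matrix, samples x channels, with column names giving
#'   channel labels. A plain vector is treated as a single channel.
#' @param rate Sampling rate in Hz (> 0).
#' @param channels Optional character vector of channel labels; overrides
#'   `colnames(signals)`.
#' @param lights_off Lights-off time in seconds from record start (default 0);
#'   must lie within the record.
#' @param subject_id Subject identifier.
#' @param group Group tag: `"exposed"`, `"sham"` or `"unknown"`.
#'
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(signals, rate, channels = NULL, lights_off = 0,
                          subject_id = "s01", group = "unknown") {
  if (is.vector(signals)) signals <- matrix(signals, ncol = 1)
  signals <- as.matrix(signals)
  storage.mode(signals) <- "double"
  if (!is.null(channels)) colnames(signals) <- channels
  if (is.null(colnames(signals)))
    colnames(signals) <- paste0("ch", seq_len(ncol(signals)))
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("`rate` must be a single positive number", call. = FALSE)
  dur <- nrow(signals) / rate
  if (lights_off < 0 || lights_off > dur)
    stop("`lights_off` must lie within the record (0 to ", dur, " s)",
         call. = FALSE)
  group <- match.arg(group, c("exposed", "sham", "unknown"))
  structure(
    list(signals = signals, rate = rate, lights_off = lights_off,
         subject_id = subject_id, group = group,
         processing = character()),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s [%s]: %d channel(s) x %.1f s @ %g Hz\n",
              x$subject_id, x$group, ncol(x$signals),
              nrow(x$signals) / x$rate, x$rate))
  cat("  channels:", paste(colnames(x$signals), collapse = ", "), "\n")
  if (length(x$processing))
    cat("  processing:", paste(x$processing, collapse = " -> "), "\n")
  invisible(x)
}

#' @export
duration.eeg_recording <- function(x) nrow(x$signals) / x$rate

#' Recording duration in seconds
#' @param x An `eeg_recording`.
#' @return Duration in seconds.
#' @export
duration <- function(x) UseMethod("duration")

rec_channel <- function(rec, channel) {
  if (!channel %in% colnames(rec$signals))
    stop("channel '", channel, "' not present in recording", call. = FALSE)
  rec$signals[, channel]
}

eog_channels <- function(rec) grep("^EOG", colnames(rec$signals), value = TRUE)
eeg_channels <- function(rec) setdiff(colnames(rec$signals), eog_channels(rec))

#' Hypnogram: scored sleep stages per 30-s epoch
#'
#' @param stages Character vector (or factor) of stage labels, one per epoch,
#'   drawn from [stage_levels()].
#' @param epoch_sec Epoch duration in seconds (default 30, the AASM scoring
#'   unit).
#' @param lights_off_epoch 0-based index of the lights-off epoch (default 0 =
#'   record start).
#'
#' @return An object of class `hypnogram` (a character vector with
#'   attributes).
#' @export
hypnogram <- function(stages, epoch_sec = 30, lights_off_epoch = 0) {
  stages <- as.character(stages)
  bad <- setdiff(unique(stages), STAGE_LEVELS)
  if (length(bad))
    stop("unknown stage label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (lights_off_epoch < 0 || lights_off_epoch >= length(stages))
    stop("`lights_off_epoch` out of range", call. = FALSE)
  structure(stages, epoch_sec = epoch_sec,
            lights_off_epoch = as.integer(lights_off_epoch),
            class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  tab <- table(factor(unclass(x), levels = STAGE_LEVELS))
  cat(sprintf("<hypnogram> %d epochs x %g s (%.2f h)\n",
              length(x), attr(x, "epoch_sec"),
              length(x) * attr(x, "epoch_sec") / 3600))
  print(tab)
  invisible(x)
}

epoch_sec <- function(h) attr(h, "epoch_sec") %||% 30
lights_off_epoch <- function(h) attr(h, "lights_off_epoch") %||% 0L

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write hypnograms as two-column CSV
#'
#' The on-disk format is a CSV with columns `epoch_index` (0-based) and
#' `stage`.
#'
#' @param h A `hypnogram`.
#' @param path File path.
#' @param epoch_sec,lights_off_epoch Passed to [hypnogram()] when reading.
#' @return `write_hypnogram()` returns `path` invisibly; `read_hypnogram()`
#'   returns a `hypnogram`.
#' @export
write_hypnogram <- function(h, path) {
  df <- data.frame(epoch_index = seq_along(h) - 1L, stage = unclass(h))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_hypnogram
#' @export
read_hypnogram <- function(path, epoch_sec = 30, lights_off_epoch = 0) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("epoch_index", "stage") %in% names(df)))
    stop("hypnogram CSV must have columns epoch_index, stage", call. = FALSE)
  df <- df[order(df$epoch_index), ]
  hypnogram(df$stage, epoch_sec = epoch_sec,
            lights_off_epoch = lights_off_epoch)
}
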