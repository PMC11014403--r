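# Synchronized two-channel record I/O. The canonical on-disk format is a CSV
# with columns t,ppg,ecg (or ppg,ecg plus an explicit sampling rate). Sample i
# of a channel occurs at t0 + (i-1)/fs; all segment ranges are half-open.

#' Construct a single-channel physiological signal
#'
#' @param samples Numeric vector of amplitudes (length >= 2, all finite).
#' @param fs Sampling rate in Hz (> 0).
#' @param label Channel name, `"ppg"` or `"ecg"`.
#' @return Object of class `bio_signal`.
#' @export
bio_signal <- function(samples, fs, label = c("ppg", "ecg")) {
  label <- match.arg(label)
  samples <- as.numeric(samples)
  if (length(samples) < 2L) {
    stop_ppg2ecg("a signal needs at least 2 samples", "format_error")
  }
  if (!all(is.finite(samples))) {
    stop_ppg2ecg("signal contains non-finite samples", "format_error")
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop_ppg2ecg("fs must be a positive number", "format_error")
  }
  structure(list(samples = samples, fs = fs, label = label),
            class = "bio_signal")
}

#' @export
print.bio_signal <- function(x, ...) {
  cat(sprintf("<bio_signal %s: %d samples @ %g Hz (%.1f s)>\n",
              x$label, length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' Construct a synchronized PPG/ECG record
#'
#' Both channels must share the sampling rate and length (they are two views
#' of the same cardiac activity, recorded simultaneously).
#'
#' @param ppg,ecg `bio_signal` objects (or numeric vectors, with `fs`).
#' @param subject_id Subject identifier string.
#' @param t0 Start time of the first sample in seconds.
#' @param fs Sampling rate, required when channels are plain vectors.
#' @return Object of class `record_pair`.
#' @export
record_pair <- function(ppg, ecg, subject_id = "s1", t0 = 0, fs = NULL) {
  if (!inherits(ppg, "bio_signal")) ppg <- bio_signal(ppg, fs, "ppg")
  if (!inherits(ecg, "bio_signal")) ecg <- bio_signal(ecg, fs, "ecg")
  if (ppg$fs != ecg$fs) {
    stop_ppg2ecg("PPG and ECG sampling rates differ", "synchronization_error")
  }
  if (length(ppg$samples) != length(ecg$samples)) {
    stop_ppg2ecg("PPG and ECG channel lengths differ", "synchronization_error")
  }
  structure(list(ppg = ppg, ecg = ecg,
                 subject_id = as.character(subject_id), t0 = t0),
            class = "record_pair")
}

#' @export
print.record_pair <- function(x, ...) {
  cat(sprintf("<record_pair subject=%s: %d samples @ %g Hz, t0=%g s>\n",
              x$subject_id, length(x$ppg$samples), x$ppg$fs, x$t0))
  invisible(x)
}

#' Duration of a record in seconds
#' @param record A `record_pair`.
#' @return Length of each channel divided by the sampling rate.
#' @export
record_duration <- function(record) {
  length(record$ppg$samples) / record$ppg$fs
}

#' Read a synchronized PPG/ECG record from CSV
#'
#' Accepts header columns `t,ppg,ecg` or `ppg,ecg`. With a time column the
#' sampling rate is inferred from the median time step, which must be uniform
#' within 1% relative tolerance; otherwise `fs` must be supplied.
#'
#' @param path CSV file path.
#' @param fs Sampling rate in Hz; required when the file has no time column.
#' @param subject_id Subject identifier attached to the record.
#' @return A `record_pair`.
#' @export
read_record <- function(path, fs = NULL, subject_id = "s1") {
  if (!file.exists(path)) stop_ppg2ecg(paste("no such file:", path), "io_error")
  df <- utils::read.csv(path)
  if (!all(c("ppg", "ecg") %in% names(df))) {
    stop_ppg2ecg("CSV must have columns (t,ppg,ecg) or (ppg,ecg)",
                 "format_error")
  }
  t0 <- 0
  if ("t" %in% names(df)) {
    dt <- diff(df$t)
    step <- stats::median(dt)
    if (step <= 0 || any(abs(dt - step) > 0.01 * step)) {
      stop_ppg2ecg("time column is not a uniform grid (1% tolerance)",
                   "sampling_error")
    }
    fs <- 1 / step
    t0 <- df$t[1L]
  } else if (is.null(fs)) {
    stop_ppg2ecg("fs must be supplied when the CSV has no time column",
                 "sampling_error")
  }
  if (length(df$ppg) != length(df$ecg)) {
    stop_ppg2ecg("unequal channel lengths", "synchronization_error")
  }
  record_pair(df$ppg, df$ecg, subject_id = subject_id, t0 = t0, fs = fs)
}

#' Write a record to CSV
#'
#' Writes columns `t,ppg,ecg` at full double precision; the time column is
#' reconstructed from `t0` and the sampling rate, so read/write round-trips.
#'
#' @param record A `record_pair`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_record <- function(record, path) {
  n <- length(record$ppg$samples)
  df <- data.frame(
    t = record$t0 + (seq_len(n) - 1L) / record$ppg$fs,
    ppg = record$ppg$samples,
    ecg = record$ecg$samples
  )
  ok <- tryCatch({
    utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_ppg2ecg(paste("cannot write", path), "io_error")
  invisible(path)
}

#' Trim a record to a time window
#'
#' Keeps the half-open sample range `[floor(keep_start_s * fs),
#' floor(keep_end_s * fs))` on both channels, replacing manual removal of
#' distorted recording sections with a declarative, reproducible cut.
#'
#' @param record A `record_pair`.
#' @param keep_start_s,keep_end_s Window in seconds relative to the start of
#'   the record, `0 <= start < end <= duration`.
#' @return A trimmed `record_pair` with updated `t0`.
#' @export
trim_record <- function(record, keep_start_s, keep_end_s) {
  fs <- record$ppg$fs
  dur <- record_duration(record)
  if (keep_start_s < 0 || keep_start_s >= keep_end_s ||
      keep_end_s > dur + 1e-9) {
    stop_ppg2ecg("trim window must satisfy 0 <= start < end <= duration",
                 "range_error")
  }
  i0 <- floor(keep_start_s * fs)
  i1 <- floor(keep_end_s * fs)
  if (i1 - i0 < 2L) stop_ppg2ecg("trim window too short", "range_error")
  idx <- (i0 + 1L):i1
  record_pair(record$ppg$samples[idx], record$ecg$samples[idx],
              subject_id = record$subject_id,
              t0 = record$t0 + i0 / fs, fs = fs)
}
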