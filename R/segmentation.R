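# Cycle segmentation: reference-peak detection and cutting a synchronized
# record into PPG/ECG cycle pairs under the two pairing modes.
#
# "Direct" pairing takes the ECG at the same timestamps as a systolic-to-
# systolic PPG cycle, preserving R-peak timing. "Semantic" pairing takes the
# R-to-R ECG interval of the same beat, aligning morphology but nulling the
# pulse-arrival delay.

peak_time <- function(idx, record) record$t0 + (idx - 1L) / record$ppg$fs

# Topographic prominence of local maxima: height above the higher of the two
# key saddles separating the peak from higher terrain (or the signal edge).
peak_prominence <- function(x, peaks) {
  n <- length(x)
  vapply(peaks, function(p) {
    h <- x[p]
    lmin <- h
    i <- p - 1L
    while (i >= 1L && x[i] <= h) {
      if (x[i] < lmin) lmin <- x[i]
      i <- i - 1L
    }
    left <- if (i >= 1L) lmin else min(x[1L:p])
    rmin <- h
    i <- p + 1L
    while (i <= n && x[i] <= h) {
      if (x[i] < rmin) rmin <- x[i]
      i <- i + 1L
    }
    right <- if (i <= n) rmin else min(x[p:n])
    h - max(left, right)
  }, numeric(1))
}

detect_peaks_impl <- function(samples, fs, max_hr_bpm, prominence_frac,
                              kind) {
  if (!is.numeric(max_hr_bpm) || max_hr_bpm <= 30 || max_hr_bpm > 300) {
    stop_ppg2ecg("max_hr_bpm must lie in (30, 300]", "parameter_error")
  }
  if (!is.numeric(prominence_frac) || prominence_frac <= 0 ||
      prominence_frac > 1) {
    stop_ppg2ecg("prominence_frac must lie in (0, 1]", "parameter_error")
  }
  d <- diff(samples)
  cand <- which(d[-length(d)] > 0 & d[-1L] <= 0) + 1L
  cand <- cand[samples[cand] > samples[cand + 1L] |
                 samples[cand] > samples[cand - 1L]]
  rng <- diff(stats::quantile(samples, c(0.05, 0.95), names = FALSE))
  min_prom <- prominence_frac * rng
  if (length(cand) > 0L && rng > 0) {
    cand <- cand[peak_prominence(samples, cand) >= min_prom]
  } else {
    cand <- integer(0)
  }
  # enforce the refractory distance, keeping taller peaks first
  min_dist <- 60 / max_hr_bpm * fs
  kept <- integer(0)
  for (p in cand[order(samples[cand], decreasing = TRUE)]) {
    if (all(abs(kept - p) >= min_dist)) kept <- c(kept, p)
  }
  kept <- sort(kept)
  if (length(kept) < 2L) {
    stop_ppg2ecg(sprintf("fewer than 2 %s peaks detected: no cycles", kind),
                 "segmentation_error")
  }
  structure(list(indices = kept, kind = kind, fs = fs), class = "peak_train")
}

#' @export
print.peak_train <- function(x, ...) {
  cat(sprintf("<peak_train %s: %d peaks @ %g Hz>\n",
              x$kind, length(x$indices), x$fs))
  invisible(x)
}

#' Detect PPG systolic peaks
#'
#' Local maxima with a minimum inter-peak distance of `60/max_hr_bpm` seconds
#' (a heart-rate-derived refractory period) and topographic prominence of at
#' least `prominence_frac` times the robust signal range (95th minus 5th
#' percentile). Intended for smoothed signals.
#'
#' @param ppg A `bio_signal` (PPG channel).
#' @param max_hr_bpm Highest plausible heart rate, in (30, 300]; default 200.
#' @param prominence_frac Fraction of the robust range in (0, 1]; default 0.3.
#' @return A `peak_train` with 1-based sample indices.
#' @export
detect_systolic_peaks <- function(ppg, max_hr_bpm = 200, prominence_frac = 0.3) {
  detect_peaks_impl(ppg$samples, ppg$fs, max_hr_bpm, prominence_frac,
                    "systolic")
}

#' Detect ECG R peaks
#'
#' Same prominence-based detector as [detect_systolic_peaks()], applied to the
#' ECG channel: after smoothing, the R wave is the dominant positive
#' deflection of each beat. For leads with negative R polarity set
#' `polarity = "negative"` to detect on the negated channel.
#'
#' @param ecg A `bio_signal` (ECG channel).
#' @inheritParams detect_systolic_peaks
#' @param polarity `"positive"` (default) or `"negative"`.
#' @return A `peak_train` with 1-based sample indices.
#' @export
detect_r_peaks <- function(ecg, max_hr_bpm = 200, prominence_frac = 0.3,
                           polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  samples <- if (polarity == "negative") -ecg$samples else ecg$samples
  detect_peaks_impl(samples, ecg$fs, max_hr_bpm, prominence_frac, "R")
}

new_cycle_pair <- function(ppg_raw, ecg_raw, ppg_start_s, ecg_start_s, fs,
                           r_time_true_s, subject_id, mode) {
  structure(
    list(ppg_raw = ppg_raw, ecg_raw = ecg_raw,
         ppg_start_s = ppg_start_s, ecg_start_s = ecg_start_s,
         ppg_duration_s = length(ppg_raw) / fs,
         ecg_duration_s = length(ecg_raw) / fs,
         fs = fs, r_time_true_s = r_time_true_s,
         subject_id = subject_id, mode = mode),
    class = "cycle_pair"
  )
}

#' Cut a record into directly paired cycles
#'
#' For each consecutive systolic-peak pair the PPG cycle and the ECG segment
#' at the *same timestamps* are paired (half-open ranges), so the segments
#' tile the record and the R peak keeps its true position inside the cycle.
#' The ground-truth R time stored with each pair is the detected R peak
#' closest to the segment's dominant ECG maximum; it is used only for
#' evaluation.
#'
#' @param record A `record_pair`.
#' @param systolic_peaks `peak_train` from [detect_systolic_peaks()].
#' @param r_peaks `peak_train` from [detect_r_peaks()].
#' @return List of `cycle_pair` objects with `mode = "direct"`.
#' @export
segment_direct <- function(record, systolic_peaks, r_peaks) {
  s <- systolic_peaks$indices
  if (length(s) < 2L) stop_ppg2ecg("need >= 2 systolic peaks",
                                   "segmentation_error")
  fs <- record$ppg$fs
  r_times <- peak_time(r_peaks$indices, record)
  lapply(seq_len(length(s) - 1L), function(i) {
    idx <- s[i]:(s[i + 1L] - 1L)
    ecg_seg <- record$ecg$samples[idx]
    peak_abs <- idx[which.max(ecg_seg)]
    r_true <- r_times[which.min(abs(r_times - peak_time(peak_abs, record)))]
    t_start <- peak_time(s[i], record)
    new_cycle_pair(record$ppg$samples[idx], ecg_seg,
                   ppg_start_s = t_start, ecg_start_s = t_start, fs = fs,
                   r_time_true_s = r_true, subject_id = record$subject_id,
                   mode = "direct")
  })
}

#' Cut a record into semantically aligned cycles
#'
#' Each systolic-to-systolic PPG cycle `[s_i, s_{i+1})` is paired with the
#' R-to-R ECG interval `[R_j, R_{j+1})` of the same beat, where `R_j` is the
#' latest R peak at or before `s_i` (the R peak precedes its systolic peak by
#' the pulse-arrival time). Cycles with no governing R peak, no closing
#' `R_{j+1}`, or whose R interval is already claimed by an earlier cycle are
#' dropped, keeping the pairing one-to-one.
#'
#' @inheritParams segment_direct
#' @return List of `cycle_pair` objects with `mode = "semantic"`.
#' @export
segment_semantic <- function(record, systolic_peaks, r_peaks) {
  s <- systolic_peaks$indices
  r <- r_peaks$indices
  if (length(s) < 2L || length(r) < 2L) {
    stop_ppg2ecg("need >= 2 systolic and >= 2 R peaks", "segmentation_error")
  }
  fs <- record$ppg$fs
  used_r <- integer(0)
  out <- list()
  for (i in seq_len(length(s) - 1L)) {
    j <- findInterval(s[i], r)      # latest R at or before s_i
    if (j < 1L || j >= length(r)) next
    if (j %in% used_r) next         # doubled assignment: keep the earlier cycle
    used_r <- c(used_r, j)
    ppg_idx <- s[i]:(s[i + 1L] - 1L)
    ecg_idx <- r[j]:(r[j + 1L] - 1L)
    out[[length(out) + 1L]] <- new_cycle_pair(
      record$ppg$samples[ppg_idx], record$ecg$samples[ecg_idx],
      ppg_start_s = peak_time(s[i], record),
      ecg_start_s = peak_time(r[j], record), fs = fs,
      r_time_true_s = peak_time(r[j], record),
      subject_id = record$subject_id, mode = "semantic")
  }
  if (length(out) == 0L) {
    stop_ppg2ecg("no PPG cycle could be paired with an R-R interval",
                 "segmentation_error")
  }
  out
}

#' Drop cycles with implausible durations
#'
#' Guards the fixed-length resampling step against artifact cycles (missed or
#' spurious peaks). Defaults correspond to roughly 30-180 beats per minute.
#'
#' @param pairs List of `cycle_pair` objects.
#' @param min_dur_s,max_dur_s Admissible PPG cycle duration in seconds.
#' @return The surviving pairs, order preserved.
#' @export
filter_cycles <- function(pairs, min_dur_s = 0.33, max_dur_s = 2.0) {
  if (min_dur_s >= max_dur_s) {
    stop_ppg2ecg("min_dur_s must be below max_dur_s", "parameter_error")
  }
  keep <- vapply(pairs, function(p) {
    p$ppg_duration_s >= min_dur_s && p$ppg_duration_s <= max_dur_s
  }, logical(1))
  pairs[keep]
}

#' Segment a smoothed record into cycle pairs
#'
#' Convenience wrapper: peak detection on both channels, pairing in the
#' requested mode, and duration filtering.
#'
#' @param record A (smoothed) `record_pair`.
#' @param mode `"direct"` or `"semantic"`.
#' @param max_hr_bpm,prominence_frac Detector parameters, see
#'   [detect_systolic_peaks()].
#' @param min_dur_s,max_dur_s Duration filter, see [filter_cycles()].
#' @param ecg_polarity R-wave polarity, see [detect_r_peaks()].
#' @return List of `cycle_pair` objects.
#' @export
segment_record <- function(record, mode = c("semantic", "direct"),
                           max_hr_bpm = 200, prominence_frac = 0.3,
                           min_dur_s = 0.33, max_dur_s = 2.0,
                           ecg_polarity = "positive") {
  mode <- match.arg(mode)
  sp <- detect_systolic_peaks(record$ppg, max_hr_bpm, prominence_frac)
  rp <- detect_r_peaks(record$ecg, max_hr_bpm, prominence_frac, ecg_polarity)
  pairs <- if (mode == "direct") {
    segment_direct(record, sp, rp)
  } else {
    segment_semantic(record, sp, rp)
  }
  filter_cycles(pairs, min_dur_s, max_dur_s)
}
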