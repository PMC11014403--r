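# Paired PPG/ECG waveform simulator with analytic ground truth.
#
# Each beat's ECG is a sum of five Gaussian waves (P, Q, R, S, T) placed
# around the R time; the PPG is a systolic (plus optional dicrotic) Gaussian
# delayed by the pulse-arrival time (PAT). Beat-to-beat RR intervals follow a
# first-order autoregressive process, optionally overridden by an abrupt
# heart-rate burst. QRS offsets and widths are fixed in seconds (the QRS does
# not stretch with heart rate), while P/T offsets and the PPG wave widths
# scale with the RR interval, so normalized cycle shapes vary with heart
# rate as they do physiologically.

default_morph <- function() {
  list(
    # ECG wave amplitudes (relative to R = 1)
    p_amp = 0.12, q_amp = -0.12, r_amp = 1.0, s_amp = -0.22, t_amp = 0.32,
    # ECG wave positions: QRS in seconds around R, P/T as fractions of RR
    p_off_frac = -0.19, q_off_s = -0.035, s_off_s = 0.035, t_off_frac = 0.30,
    # ECG wave widths (Gaussian sd, seconds)
    p_sd_s = 0.030, q_sd_s = 0.012, r_sd_s = 0.013, s_sd_s = 0.012,
    t_sd_s = 0.060,
    # PPG waves: amplitudes, widths and dicrotic offset as fractions of RR
    sys_amp = 1.0, sys_sd_frac = 0.13,
    dicrotic_amp = 0.35, dicrotic_off_frac = 0.38, dicrotic_sd_frac = 0.12
  )
}

#' Simulation configuration
#'
#' Defaults describe a resting adult-like subject at 300 Hz: 70 beats per
#' minute with beat-to-beat variability of 3.3 BPM (an RR standard deviation
#' of about 40 ms at this rate), a pulse-arrival time of 0.25 s with 20 ms
#' jitter, and 20 dB additive Gaussian noise per channel. `hr_burst` injects
#' an abrupt heart-rate excursion (e.g. to 100 BPM) for a fixed period, the
#' kind of transient an evaluation split must represent in both training and
#' test data.
#'
#' @param fs Sampling rate in Hz.
#' @param duration_s Record duration in seconds.
#' @param hr_mean_bpm Mean heart rate, in `[30, 220]`.
#' @param hr_sd_bpm Beat-to-beat heart-rate variability (BPM).
#' @param hr_burst `NULL` or `list(onset_s=, burst_bpm=, length_s=)`.
#' @param pat_s Mean pulse-arrival delay R peak -> systolic peak, seconds.
#' @param pat_sd_s Beat-to-beat jitter of the delay, seconds.
#' @param noise_snr_db Per-channel additive-noise SNR in dB (`Inf` = none).
#' @param morph Morphology template parameters; see source of
#'   `ppg2ecg:::default_morph` for the fields.
#' @param subject_id Subject identifier.
#' @param seed Integer seed; every draw the simulator makes is governed by it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(fs = 300, duration_s = 60, hr_mean_bpm = 70,
                       hr_sd_bpm = 3.3, hr_burst = NULL, pat_s = 0.25,
                       pat_sd_s = 0.02, noise_snr_db = 20,
                       morph = default_morph(), subject_id = "sim1",
                       seed = 1L) {
  if (hr_mean_bpm < 30 || hr_mean_bpm > 220) {
    stop_ppg2ecg("hr_mean_bpm must lie in [30, 220]", "parameter_error")
  }
  if (pat_s < 0) stop_ppg2ecg("pat_s must be >= 0", "parameter_error")
  morph <- utils::modifyList(default_morph(), morph)
  structure(list(fs = fs, duration_s = duration_s, hr_mean_bpm = hr_mean_bpm,
                 hr_sd_bpm = hr_sd_bpm, hr_burst = hr_burst, pat_s = pat_s,
                 pat_sd_s = pat_sd_s, noise_snr_db = noise_snr_db,
                 morph = morph, subject_id = subject_id,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a beat-to-beat RR interval series
#'
#' First-order autoregressive deviations (lag-1 coefficient 0.6) around the
#' mean RR interval `60 / hr_mean_bpm`; the BPM variability is mapped to an
#' RR standard deviation via `60 * hr_sd / hr_mean^2`. During a configured
#' burst the mean switches to the burst rate. Enough intervals are generated
#' to cover `duration_s`; the series is fully determined by the seed.
#'
#' @param config A [sim_config()].
#' @return Numeric vector of RR intervals in seconds.
#' @export
simulate_rr_series <- function(config) {
  with_seed(config$seed, {
    mu0 <- 60 / config$hr_mean_bpm
    rr_sd <- 60 * config$hr_sd_bpm / config$hr_mean_bpm^2
    phi <- 0.6
    innov_sd <- rr_sd * sqrt(1 - phi^2)
    rr <- numeric(0)
    t <- 0
    d <- 0
    while (t < config$duration_s + 2) {
      mu <- mu0
      b <- config$hr_burst
      if (!is.null(b) && t >= b$onset_s && t < b$onset_s + b$length_s) {
        mu <- 60 / b$burst_bpm
      }
      d <- phi * d + if (innov_sd > 0) stats::rnorm(1, 0, innov_sd) else 0
      r <- max(0.25, min(2.5, mu + d))
      rr <- c(rr, r)
      t <- t + r
    }
    rr
  })
}

add_gauss <- function(y, t, center, amp, sd) {
  if (amp == 0 || sd <= 0) return(y)
  n <- length(y)
  fs <- 1 / (t[2L] - t[1L])
  i0 <- max(1L, floor((center - 4 * sd) * fs) + 1L)
  i1 <- min(n, ceiling((center + 4 * sd) * fs) + 1L)
  if (i0 > i1) return(y)
  idx <- i0:i1
  y[idx] <- y[idx] + amp * exp(-(t[idx] - center)^2 / (2 * sd^2))
  y
}

#' Simulate a synchronized PPG/ECG record with ground-truth annotations
#'
#' See the package-level description of the generative model. The R wave is
#' the global per-beat maximum of the ECG, so prominence-based detection has
#' a well-defined target; systolic times equal R times plus the (jittered)
#' pulse-arrival delay, beat for beat.
#'
#' @param config A [sim_config()].
#' @return Object of class `sim_record`: `record` (a `record_pair`),
#'   `r_times_s`, `systolic_times_s`, `rr_series_s`, `clean` (noise-free
#'   channels, for calibration checks), and `config`.
#' @export
simulate_record <- function(config) {
  rr <- simulate_rr_series(config)
  m <- config$morph
  fs <- config$fs
  n <- round(config$duration_s * fs)
  t <- (seq_len(n) - 1L) / fs
  r_times <- 0.4 + cumsum(c(0, rr[-length(rr)]))
  keep <- r_times > 0.1 & (r_times + config$pat_s) < config$duration_s - 0.15
  r_times <- r_times[keep]
  rr_next <- rr[keep]
  rr_prev <- c(rr_next[1L], rr_next[-length(rr_next)])
  # PAT varies slowly from beat to beat (respiratory and blood-pressure
  # modulation), so its jitter is a smooth AR(1) process with stationary
  # sd pat_sd_s, not white noise.
  pat <- with_seed(config$seed + 1L, {
    if (config$pat_sd_s > 0) {
      phi <- 0.95
      e <- stats::rnorm(length(r_times), 0, config$pat_sd_s * sqrt(1 - phi^2))
      d <- stats::filter(e, phi, method = "recursive")
      config$pat_s + as.numeric(d)
    } else {
      rep(config$pat_s, length(r_times))
    }
  })
  pat <- pmax(0.05, pat)
  s_times <- r_times + pat
  ecg <- numeric(n)
  ppg <- numeric(n)
  for (i in seq_along(r_times)) {
    r <- r_times[i]
    ecg <- add_gauss(ecg, t, r + m$p_off_frac * rr_prev[i], m$p_amp, m$p_sd_s)
    ecg <- add_gauss(ecg, t, r + m$q_off_s, m$q_amp, m$q_sd_s)
    ecg <- add_gauss(ecg, t, r, m$r_amp, m$r_sd_s)
    ecg <- add_gauss(ecg, t, r + m$s_off_s, m$s_amp, m$s_sd_s)
    ecg <- add_gauss(ecg, t, r + m$t_off_frac * rr_next[i], m$t_amp, m$t_sd_s)
    ppg <- add_gauss(ppg, t, s_times[i], m$sys_amp,
                     m$sys_sd_frac * rr_next[i])
    ppg <- add_gauss(ppg, t, s_times[i] + m$dicrotic_off_frac * rr_next[i],
                     m$dicrotic_amp, m$dicrotic_sd_frac * rr_next[i])
  }
  clean <- list(ppg = ppg, ecg = ecg)
  if (is.finite(config$noise_snr_db)) {
    with_seed(config$seed + 2L, {
      snr_lin <- 10^(-config$noise_snr_db / 10)
      ppg <- ppg + stats::rnorm(n, 0, sqrt(stats::var(clean$ppg) * snr_lin))
      ecg <- ecg + stats::rnorm(n, 0, sqrt(stats::var(clean$ecg) * snr_lin))
    })
  }
  record <- record_pair(ppg, ecg, subject_id = config$subject_id, t0 = 0,
                        fs = fs)
  structure(list(record = record, r_times_s = r_times,
                 systolic_times_s = s_times, rr_series_s = rr_next,
                 clean = clean, config = config),
            class = "sim_record")
}

#' @export
print.sim_record <- function(x, ...) {
  cat(sprintf("<sim_record subject=%s: %d beats, %.0f s @ %g Hz>\n",
              x$config$subject_id, length(x$r_times_s),
              x$config$duration_s, x$config$fs))
  invisible(x)
}

#' Simulate coefficient-space linear cycle pairs
#'
#' Oracle fixture for the transfer model: draws `n` smooth PPG-like cycles,
#' takes their leading `n_ppg` DCT coefficients `X`, fixes a random map `M`
#' (`n_ppg x n_ecg`), and builds "ECG" cycles as the zero-padded inverse DCT
#' of `X %*% M` plus optional Gaussian noise. With zero noise the ridge fit
#' must recover `M` exactly (up to the vanishing penalty).
#'
#' @param n Number of cycle pairs (`n >= n_ppg` for a full-rank design).
#' @param n_ppg,n_ecg Coefficient-space dimensions.
#' @param L Cycle length.
#' @param noise_sd Amplitude of additive Gaussian noise on the ECG cycles.
#' @param seed Integer seed.
#' @return List with matrices `ppg`, `ecg` (one cycle per row) and the true
#'   map `M`.
#' @export
simulate_linear_pairs <- function(n, n_ppg = 11L, n_ecg = 100L, L = 300L,
                                  noise_sd = 0, seed = 1L) {
  if (n < n_ppg) {
    warning("n < n_ppg: the design is rank-deficient; use gamma > 0")
  }
  with_seed(seed, {
    u <- (seq_len(L) - 1L) / L
    ppg <- t(vapply(seq_len(n), function(i) {
      c1 <- stats::runif(1, 0.15, 0.45)
      w1 <- stats::runif(1, 0.08, 0.18)
      a2 <- stats::runif(1, 0.2, 0.5)
      c2 <- c1 + stats::runif(1, 0.25, 0.45)
      w2 <- stats::runif(1, 0.10, 0.20)
      v <- exp(-(u - c1)^2 / (2 * w1^2)) + a2 * exp(-(u - c2)^2 / (2 * w2^2))
      for (k in 1:4) v <- v + stats::rnorm(1, 0, 0.02) * cos(pi * k * u)
      v
    }, numeric(L)))
    X <- dct_rows(ppg, n_ppg)
    M <- matrix(stats::rnorm(n_ppg * n_ecg), n_ppg, n_ecg) / sqrt(n_ppg)
    Yc <- X %*% M
    ecg <- t(vapply(seq_len(n), function(i) {
      dct_inverse(Yc[i, ], L = L) + if (noise_sd > 0) {
        stats::rnorm(L, 0, noise_sd)
      } else 0
    }, numeric(L)))
    list(ppg = ppg, ecg = ecg, M = M)
  })
}

#' Simulate a population of subjects with person-specific physiology
#'
#' Each subject gets its own morphology template, pulse-arrival time and mean
#' heart rate, obtained by log-normal perturbation of the base configuration
#' with spread `subject_variation` (0 = identical subjects). This is the
#' fixture behind the personalized-versus-general comparison: person-specific
#' PPG-to-ECG maps are exactly what makes a general model underperform.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param base Base [sim_config()] shared by all subjects.
#' @param subject_variation Log-scale spread of the perturbations; default
#'   0.3.
#' @param seed Integer seed.
#' @return List of `sim_record` objects, one per subject.
#' @export
simulate_subject_population <- function(n_subjects, base = sim_config(),
                                        subject_variation = 0.3, seed = 1L) {
  if (!is_count(n_subjects) || n_subjects < 2L) {
    stop_ppg2ecg("need at least 2 subjects", "parameter_error")
  }
  perturb <- with_seed(seed, {
    lapply(seq_len(n_subjects), function(s) {
      stats::rnorm(8)
    })
  })
  lapply(seq_len(n_subjects), function(s) {
    z <- perturb[[s]]
    v <- subject_variation
    m <- base$morph
    m$p_amp <- m$p_amp * exp(v * z[1L])
    m$q_amp <- m$q_amp * exp(v * z[2L])
    m$s_amp <- m$s_amp * exp(v * z[3L])
    m$t_amp <- m$t_amp * exp(v * z[4L])
    m$t_sd_s <- m$t_sd_s * exp(0.5 * v * z[5L])
    m$dicrotic_amp <- m$dicrotic_amp * exp(v * z[6L])
    cfg <- sim_config(
      fs = base$fs, duration_s = base$duration_s,
      hr_mean_bpm = min(110, max(50, base$hr_mean_bpm * exp(0.15 * v * z[7L]))),
      hr_sd_bpm = base$hr_sd_bpm, hr_burst = base$hr_burst,
      pat_s = min(0.45, max(0.12, base$pat_s * exp(0.5 * v * z[8L]))),
      pat_sd_s = base$pat_sd_s, noise_snr_db = base$noise_snr_db,
      morph = m, subject_id = sprintf("sim%02d", s),
      seed = seed + 1000L * s)
    simulate_record(cfg)
  })
}
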