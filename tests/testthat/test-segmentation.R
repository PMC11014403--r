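# 60 s noiseless record shared by segmentation tests
seg_fixture <- function() {
  cached("seg_clean", prepared_record(
    sim_config(duration_s = 60, seed = 11L, noise_snr_db = Inf,
               pat_sd_s = 0)))
}

test_that("peak detection recovers every simulated beat on clean data", {
  fx <- seg_fixture()
  n_beats <- length(fx$sim$r_times_s)
  expect_gte(length(fx$sys$indices), n_beats - 1L)
  expect_lte(length(fx$sys$indices), n_beats + 1L)
  expect_identical(length(fx$r$indices), n_beats)

  r_det <- (fx$r$indices - 1) / 300
  err <- vapply(r_det, function(x) min(abs(x - fx$sim$r_times_s)), numeric(1))
  expect_lt(max(err), 1.5 / 300)  # within about one sample

  expect_true(all(diff(fx$sys$indices) > 0))
  expect_error(detect_systolic_peaks(bio_signal(rep(1, 100), 300, "ppg")),
               class = "segmentation_error")
})

test_that("detection stays accurate at 20 dB SNR", {
  fx <- cached("seg_noisy", prepared_record(
    sim_config(duration_s = 60, seed = 12L, noise_snr_db = 20)))
  r_det <- (fx$r$indices - 1) / 300
  err <- vapply(r_det, function(x) min(abs(x - fx$sim$r_times_s)), numeric(1))
  expect_lt(median(err), 0.010)

  s_det <- (fx$sys$indices - 1) / 300
  errs <- vapply(s_det, function(x) min(abs(x - fx$sim$systolic_times_s)),
                 numeric(1))
  expect_lt(median(errs), 0.020)
})

test_that("negative-polarity ECG is detected on the negated channel", {
  fx <- seg_fixture()
  flipped <- bio_signal(-fx$rec$ecg$samples, 300, "ecg")
  rp <- detect_r_peaks(flipped, polarity = "negative")
  expect_identical(rp$indices, fx$r$indices)
  # without the polarity flag the dominant deflection is missed
  wrong <- detect_r_peaks(flipped)
  expect_false(identical(wrong$indices, fx$r$indices))
})

test_that("direct segmentation tiles the record between systolic peaks", {
  fx <- seg_fixture()
  pairs <- segment_direct(fx$rec, fx$sys, fx$r)
  K <- length(fx$sys$indices)
  expect_length(pairs, K - 1L)

  tiled <- unlist(lapply(pairs, function(p) p$ppg_raw))
  span <- fx$rec$ppg$samples[fx$sys$indices[1L]:(fx$sys$indices[K] - 1L)]
  expect_identical(tiled, span)

  # shared timestamps and durations
  for (p in pairs[c(1, 10, length(pairs))]) {
    expect_identical(p$ppg_start_s, p$ecg_start_s)
    expect_identical(p$ppg_duration_s, p$ecg_duration_s)
  }

  # with constant PAT each segment's true R sits PAT before the systolic
  # boundary of the *next* beat
  r_off <- vapply(pairs, function(p) {
    p$ppg_start_s + p$ppg_duration_s - p$r_time_true_s
  }, numeric(1))
  expect_lt(median(abs(r_off - 0.25)), 2 / 300)
})

test_that("semantic segmentation starts cycles at R and pairs one-to-one", {
  fx <- seg_fixture()
  direct <- segment_direct(fx$rec, fx$sys, fx$r)
  sem <- segment_semantic(fx$rec, fx$sys, fx$r)
  expect_gte(length(sem), length(direct) - 1L)

  r_starts <- vapply(sem, function(p) p$ecg_start_s, numeric(1))
  expect_identical(anyDuplicated(r_starts), 0L)
  for (p in sem[c(1, 5, length(sem))]) {
    expect_identical(which.max(p$ecg_raw), 1L)
    expect_identical(p$r_time_true_s, p$ecg_start_s)
  }
})

test_that("a missed R peak drops only the affected cycle", {
  fx <- seg_fixture()
  full <- segment_semantic(fx$rec, fx$sys, fx$r)
  drop_j <- 10L
  r2 <- structure(list(indices = fx$r$indices[-drop_j], kind = "R", fs = 300),
                  class = "peak_train")
  broken <- segment_semantic(fx$rec, fx$sys, r2)
  expect_identical(length(broken), length(full) - 1L)
  starts <- vapply(broken, function(p) p$ecg_start_s, numeric(1))
  expect_identical(anyDuplicated(starts), 0L)
})

test_that("duration filtering keeps exactly the in-range cycles", {
  fx <- seg_fixture()
  pairs <- segment_direct(fx$rec, fx$sys, fx$r)
  expect_identical(filter_cycles(pairs), pairs)

  durs <- vapply(pairs, function(p) p$ppg_duration_s, numeric(1))
  lo <- quantile(durs, 0.25, names = FALSE)
  hi <- quantile(durs, 0.75, names = FALSE)
  kept <- filter_cycles(pairs, lo, hi)
  expect_identical(length(kept), sum(durs >= lo & durs <= hi))

  # an artificial 5 s artifact cycle is removed
  fake <- pairs[[1L]]
  fake$ppg_duration_s <- 5
  expect_identical(length(filter_cycles(c(pairs, list(fake)))), length(pairs))
  expect_error(filter_cycles(pairs, 2, 1), class = "parameter_error")
})
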