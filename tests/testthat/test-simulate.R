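test_that("the RR series hits its mean, variability and determinism targets", {
  cfg0 <- sim_config(duration_s = 60, hr_sd_bpm = 0, seed = 41L)
  rr0 <- simulate_rr_series(cfg0)
  expect_true(all(abs(rr0 - 60 / 70) < 1e-12))

  cfg <- sim_config(duration_s = 600, hr_mean_bpm = 70, hr_sd_bpm = 3,
                    seed = 42L)
  rr <- simulate_rr_series(cfg)
  expect_identical(simulate_rr_series(cfg), rr)
  expect_lt(abs(mean(rr) - 60 / 70) / (60 / 70), 0.02)
  expect_gt(cor(rr[-1], rr[-length(rr)]), 0)  # AR(1) memory

  # burst overrides the mean rate during its window
  cfgb <- sim_config(duration_s = 120, hr_sd_bpm = 0, seed = 43L,
                     hr_burst = list(onset_s = 60, burst_bpm = 100,
                                     length_s = 20))
  rrb <- simulate_rr_series(cfgb)
  expect_setequal(round(unique(rrb), 10), round(c(60 / 70, 60 / 100), 10))
})

test_that("annotations are consistent: one R and one systolic per beat", {
  sim <- cached("sim_clean", simulate_record(
    sim_config(duration_s = 60, seed = 44L, noise_snr_db = Inf,
               pat_sd_s = 0)))
  expect_identical(length(sim$r_times_s), length(sim$systolic_times_s))
  expect_true(all(diff(sim$r_times_s) > 0))
  expect_equal(sim$systolic_times_s - sim$r_times_s,
               rep(0.25, length(sim$r_times_s)), tolerance = 1e-12)

  # R is the dominant per-beat ECG maximum: the clean-channel argmax near
  # each annotated R time is the R sample itself
  rec <- sim$record
  for (r in sim$r_times_s[c(1, 20, 40)]) {
    idx <- round(r * 300) + 1L
    win <- (idx - 60L):(idx + 60L)
    expect_lt(abs(win[which.max(sim$clean$ecg[win])] - idx), 2L)
  }
})

test_that("seeds fully determine records; noise follows the SNR target", {
  cfg <- sim_config(duration_s = 30, seed = 45L)
  a <- simulate_record(cfg)
  b <- simulate_record(cfg)
  expect_identical(a$record$ppg$samples, b$record$ppg$samples)

  cfg2 <- sim_config(duration_s = 30, seed = 46L, hr_sd_bpm = 0)
  cfg3 <- sim_config(duration_s = 30, seed = 47L, hr_sd_bpm = 0)
  r2 <- simulate_record(cfg2)
  r3 <- simulate_record(cfg3)
  expect_identical(length(r2$r_times_s), length(r3$r_times_s))
  expect_false(identical(r2$record$ppg$samples, r3$record$ppg$samples))

  # realized noise power within 10% of the configured 20 dB target
  sim <- simulate_record(sim_config(duration_s = 120, seed = 48L,
                                    noise_snr_db = 20))
  for (ch in c("ppg", "ecg")) {
    noise <- sim$record[[ch]]$samples - sim$clean[[ch]]
    target <- var(sim$clean[[ch]]) * 10^(-2)
    expect_lt(abs(var(noise) - target) / target, 0.10)
  }
})

test_that("planted linear pairs are recovered and support the identity case", {
  sim <- simulate_linear_pairs(60, n_ppg = 9L, n_ecg = 9L, L = 150L,
                               noise_sd = 0, seed = 49L)
  # with M replaced by the identity the ECG is the DCT-truncated PPG
  Yc <- ppg2ecg:::dct_rows(sim$ppg, 9L)
  recon <- t(apply(Yc, 1L, dct_inverse, L = 150L))
  sim_id <- simulate_linear_pairs(60, 9L, 9L, 150L, 0, seed = 49L)
  expect_identical(sim$ppg, sim_id$ppg)  # seed determinism
  expect_warning(simulate_linear_pairs(5, n_ppg = 9L, n_ecg = 4L, L = 50L),
                 "rank")
})

test_that("subject populations are deterministic and heterogeneous", {
  base <- sim_config(duration_s = 20)
  pop <- simulate_subject_population(3L, base, subject_variation = 0.4,
                                     seed = 50L)
  pop2 <- simulate_subject_population(3L, base, subject_variation = 0.4,
                                      seed = 50L)
  expect_identical(pop[[2L]]$record$ecg$samples,
                   pop2[[2L]]$record$ecg$samples)
  expect_identical(vapply(pop, function(s) s$config$subject_id, character(1)),
                   c("sim01", "sim02", "sim03"))
  pats <- vapply(pop, function(s) s$config$pat_s, numeric(1))
  expect_gt(max(pats) - min(pats), 0)

  none <- simulate_subject_population(3L, base, subject_variation = 0,
                                      seed = 50L)
  pats0 <- vapply(none, function(s) s$config$pat_s, numeric(1))
  expect_equal(pats0, rep(base$pat_s, 3L))
  expect_error(simulate_subject_population(1L, base),
               class = "parameter_error")
})
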