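test_that("pearson matches the covariance formula and flags constants", {
  a <- c(1, 2, 3, 4)
  b <- c(1, 2, 3, 5)
  oracle <- function(a, b) {
    n <- length(a)
    cv <- sum((a - mean(a)) * (b - mean(b))) / (n - 1)
    cv / (sd(a) * sd(b))
  }
  expect_equal(pearson(a, b), oracle(a, b), tolerance = 1e-12)
  expect_equal(pearson(a, a), 1)
  expect_equal(pearson(a, -a), -1)
  expect_true(is.na(pearson(a, rep(2, 4))))
  expect_error(pearson(a, 1:3), class = "parameter_error")

  # invariant under positive affine transforms
  x <- withr::with_seed(8, rnorm(50))
  y <- withr::with_seed(9, rnorm(50))
  expect_equal(pearson(3 * x + 2, y), pearson(x, 0.5 * y - 7),
               tolerance = 1e-12)
})

test_that("rrmse matches its definition", {
  g <- withr::with_seed(10, rnorm(30))
  r <- withr::with_seed(11, rnorm(30))
  expect_equal(rrmse(r, g), sqrt(sum((r - g)^2)) / sqrt(sum(g^2)),
               tolerance = 1e-12)
  expect_equal(rrmse(g, g), 0)
  expect_equal(rrmse(rep(0, 30), g), 1)
  expect_true(is.na(rrmse(g, rep(0, 30))))
})

test_that("R-peak delay follows the fraction arithmetic of the cycle span", {
  L <- 300L
  # true R at 40% of a 1 s cycle starting at t = 100
  pair <- manual_pair(100, 1, 100.4)
  recon <- rep(0, L)
  recon[0.4 * L + 1L] <- 1
  expect_equal(r_peak_delay(recon, pair), 0, tolerance = 1e-12)

  # shift the argmax by exactly 30 resampled samples -> 0.1 s
  shifted <- rep(0, L)
  shifted[0.4 * L + 31L] <- 1
  expect_equal(r_peak_delay(shifted, pair), 0.1, tolerance = 1e-12)

  # self-agreement: argmax of the true cycle lands within quantization
  fx <- cached("ev_clean", prepared_record(
    sim_config(duration_s = 30, seed = 13L, noise_snr_db = Inf,
               pat_sd_s = 0)))
  pairs <- segment_direct(fx$rec, fx$sys, fx$r)
  p <- pairs[[5L]]
  recon_true <- resample_linear(p$ecg_raw, L)
  expect_lt(r_peak_delay(recon_true, p), 1 / 300 + 2 * p$ppg_duration_s / L)

  p$r_time_true_s <- NA_real_
  expect_error(r_peak_delay(recon_true, p), class = "evaluation_error")
})

test_that("sequential k-fold plans are contiguous, disjoint and exhaustive", {
  pairs <- replicate(100, manual_pair(0, 1, 0.4), simplify = FALSE)
  plan <- build_general_cv(pairs, 5L)
  expect_length(plan$folds, 5L)
  tests <- lapply(plan$folds, `[[`, "test")
  expect_true(all(vapply(tests, length, integer(1)) == 20L))
  expect_true(all(vapply(tests, function(x) all(diff(x) == 1L), logical(1))))
  expect_identical(sort(unlist(tests)), 1:100)
  for (f in plan$folds) expect_length(intersect(f$train, f$test), 0L)
  expect_error(build_general_cv(pairs, 101L), class = "parameter_error")
})

test_that("sequential folds rarely straddle subject boundaries", {
  pairs <- unlist(lapply(1:3, function(s) {
    replicate(50, {
      p <- manual_pair(0, 1, 0.4)
      p$subject_id <- paste0("s", s)
      p
    }, simplify = FALSE)
  }), recursive = FALSE)
  plan <- build_general_cv(pairs, 5L)
  subj <- vapply(pairs, function(p) p$subject_id, character(1))
  n_mixed <- sum(vapply(plan$folds, function(f) {
    length(unique(subj[f$test])) > 1L
  }, logical(1)))
  expect_lte(n_mixed, 2L)
})

test_that("pooled sliding windows split each window 80/20 in order", {
  pairs <- replicate(40, manual_pair(0, 1, 0.4), simplify = FALSE)
  plan <- build_personalized_windows(pairs, window = 20L, train_frac = 0.8,
                                     stride = 20L)
  f <- plan$folds[[1L]]
  expect_identical(f$train, c(1:16, 21:36))
  expect_identical(f$test, c(17:20, 37:40))
  expect_length(intersect(f$train, f$test), 0L)

  # trailing partial window is dropped
  plan2 <- build_personalized_windows(pairs[1:45], 20L)
  expect_identical(plan2$folds[[1L]]$train, f$train)
  expect_error(build_personalized_windows(pairs[1:10], 20L),
               class = "parameter_error")
})

test_that("burst cycles appear in both pooled train and test sets", {
  sim <- cached("ev_burst", simulate_record(
    sim_config(duration_s = 240, seed = 14L,
               hr_burst = list(onset_s = 150, burst_bpm = 100,
                               length_s = 40))))
  rec <- smooth_record(sim$record)
  pairs <- segment_record(rec, "direct")
  plan <- build_personalized_windows(pairs, 20L)
  in_burst <- vapply(pairs, function(p) {
    p$ppg_start_s >= 150 && p$ppg_start_s < 190
  }, logical(1))
  f <- plan$folds[[1L]]
  expect_gt(sum(in_burst[f$train]), 0L)
  expect_gt(sum(in_burst[f$test]), 0L)
})

test_that("LOSO plans test each subject exactly once", {
  pairs <- unlist(lapply(1:5, function(s) {
    replicate(10, {
      p <- manual_pair(0, 1, 0.4)
      p$subject_id <- paste0("s", s)
      p
    }, simplify = FALSE)
  }), recursive = FALSE)
  plan <- build_loso(pairs)
  expect_length(plan$folds, 5L)
  subj <- vapply(pairs, function(p) p$subject_id, character(1))
  for (f in plan$folds) {
    expect_length(intersect(subj[f$train], subj[f$test]), 0L)
  }
  expect_identical(sort(unlist(lapply(plan$folds, `[[`, "test"))), 1:50)
  expect_error(build_loso(pairs[1:10]), class = "parameter_error")
})

test_that("run_scheme is deterministic and its aggregates recomputable", {
  fx <- cached("ev_run", prepared_record(sim_config(duration_s = 90,
                                                    seed = 15L)))
  pairs <- segment_semantic(fx$rec, fx$sys, fx$r)
  plan <- build_plan(pairs, "personalized-window")
  r1 <- run_scheme(plan, pairs)
  r2 <- run_scheme(plan, pairs)
  expect_identical(r1$per_cycle, r2$per_cycle)

  o <- r1$aggregates$overall
  expect_equal(o$mean_rho, mean(r1$per_cycle$rho, na.rm = TRUE))
  expect_equal(o$mean_r_delay_s, mean(r1$per_cycle$r_delay_s))
  expect_identical(o$n, nrow(r1$per_cycle))

  # train-only selection: coefficient counts recorded per fold
  expect_true(all(vapply(r1$selection_used, function(s) s$n_ppg >= 1,
                         logical(1))))
})

test_that("concatenation in direct mode with perfect cycles stays at rho 1", {
  fx <- cached("ev_clean30", prepared_record(
    sim_config(duration_s = 30, seed = 16L, noise_snr_db = Inf,
               pat_sd_s = 0)))
  pairs <- segment_direct(fx$rec, fx$sys, fx$r)
  # "reconstructions" = the true normalized cycles
  recons <- lapply(pairs, function(p) {
    normalize_minmax(resample_linear(p$ecg_raw, 300L))$values
  })
  cc <- concat_correlation(recons, pairs, fx$rec, ks = c(1, 4, 8))
  expect_gt(min(cc$rho), 0.995)
  expect_error(concat_correlation(recons[1:4], pairs[1:4], fx$rec, ks = 8),
               class = "parameter_error")
})
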