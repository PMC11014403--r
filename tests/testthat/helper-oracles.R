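# Shared test fixtures and independent oracles.

# Naive O(L^2) orthonormal DCT-II, written directly from the cosine sum.
naive_dct_ii <- function(x) {
  n <- length(x)
  vapply(0:(n - 1L), function(k) {
    a <- if (k == 0L) sqrt(1 / n) else sqrt(2 / n)
    a * sum(x * cos(pi * (2 * (0:(n - 1L)) + 1) * k / (2 * n)))
  }, numeric(1))
}

# Memoized simulated records so expensive fixtures are built once per file.
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) assign(key, force(expr), .fixture_cache)
  .fixture_cache[[key]]
}

# A smoothed simulated record plus detected peaks, ready for segmentation.
prepared_record <- function(cfg) {
  sim <- simulate_record(cfg)
  rec <- smooth_record(sim$record)
  list(sim = sim,
       rec = rec,
       sys = detect_systolic_peaks(rec$ppg),
       r = detect_r_peaks(rec$ecg))
}

# Hand-built cycle pair for metric arithmetic tests.
manual_pair <- function(ppg_start_s, duration_s, r_time_true_s,
                        mode = "direct", fs = 300) {
  n <- round(duration_s * fs)
  structure(list(ppg_raw = numeric(n), ecg_raw = numeric(n),
                 ppg_start_s = ppg_start_s, ecg_start_s = ppg_start_s,
                 ppg_duration_s = duration_s, ecg_duration_s = duration_s,
                 fs = fs, r_time_true_s = r_time_true_s,
                 subject_id = "manual", mode = mode),
            class = "cycle_pair")
}
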