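# Fixed-length cycle representation: linear resampling, min-max amplitude
# normalization, and orthonormal DCT-II compression.
#
# The DCT uses the orthonormal convention so that signal energy equals the
# sum of squared coefficients (Parseval), which makes the captured-energy
# truncation rule exact. Both directions are computed through a single
# length-N FFT (Makhoul's even-odd reordering) rather than an O(N^2) sum.

# Orthonormal DCT-II of a real vector via one complex FFT.
dct_ii <- function(x) {
  n <- length(x)
  if (n == 1L) return(x)
  even <- x[seq(1L, n, by = 2L)]
  odd_rev <- rev(x[seq(2L, n, by = 2L)])
  v <- c(even, odd_rev)
  V <- stats::fft(v)
  k <- 0:(n - 1L)
  g <- Re(V * exp(-1i * pi * k / (2 * n)))
  g * c(sqrt(1 / n), rep(sqrt(2 / n), n - 1L))
}

# Inverse of dct_ii (orthonormal DCT-III), again via one FFT.
idct_ii <- function(y) {
  n <- length(y)
  if (n == 1L) return(y)
  g <- y / c(sqrt(1 / n), rep(sqrt(2 / n), n - 1L))
  k <- 1:(n - 1L)
  # Reassemble the FFT of the even-odd reordered sequence from the real
  # projections g_k = Re(e^{-i pi k/(2n)} V_k) and g_{n-k} = -Im(...).
  V <- complex(length.out = n)
  V[1L] <- g[1L]
  V[k + 1L] <- exp(1i * pi * k / (2 * n)) * (g[k + 1L] - 1i * g[n - k + 1L])
  v <- Re(stats::fft(V, inverse = TRUE)) / n
  x <- numeric(n)
  n_even <- ceiling(n / 2)
  x[seq(1L, n, by = 2L)] <- v[seq_len(n_even)]
  x[seq(2L, n, by = 2L)] <- rev(v[seq(n_even + 1L, n)])
  x
}

#' Resample a cycle to a fixed length by linear interpolation
#'
#' Maps a variable-length cardiac cycle onto a uniform grid of `L` points
#' spanning the same index range, preserving both endpoints exactly. This is
#' the temporal-scaling step that makes cycles of different duration (due to
#' heart-rate variability) comparable.
#'
#' @param samples Numeric vector of at least 2 amplitude values.
#' @param L Target length (integer, at least 2); default 300.
#' @return Numeric vector of length `L`.
#' @export
#' @examples
#' resample_linear(c(0, 1, 2, 3), 7)
resample_linear <- function(samples, L = 300L) {
  if (length(samples) < 2L) {
    stop_ppg2ecg("cannot resample a cycle with fewer than 2 samples",
                 "degenerate_cycle_error")
  }
  if (!is_count(L) || L < 2L) {
    stop_ppg2ecg("L must be an integer >= 2", "parameter_error")
  }
  n <- length(samples)
  stats::approx(x = seq(0, 1, length.out = n), y = samples,
                xout = seq(0, 1, length.out = L))$y
}

#' Min-max normalize a cycle's amplitude to [0, 1]
#'
#' Returns the rescaled values together with the original range (`scale`) and
#' minimum (`offset`) so the transformation is invertible via
#' [denormalize_minmax()]. A constant cycle maps to all zeros with
#' `scale = 0`.
#'
#' @param samples Non-empty numeric vector.
#' @return List with `values` (in `[0,1]`), `scale`, `offset`.
#' @export
normalize_minmax <- function(samples) {
  if (length(samples) == 0L) {
    stop_ppg2ecg("cannot normalize an empty cycle", "parameter_error")
  }
  lo <- min(samples)
  hi <- max(samples)
  rng <- hi - lo
  if (rng == 0) {
    return(list(values = rep(0, length(samples)), scale = 0, offset = lo))
  }
  list(values = (samples - lo) / rng, scale = rng, offset = lo)
}

#' Undo min-max normalization
#'
#' @param values Normalized values.
#' @param scale,offset Range and minimum returned by [normalize_minmax()].
#' @return Numeric vector on the original amplitude scale.
#' @export
denormalize_minmax <- function(values, scale, offset) {
  values * scale + offset
}

#' Forward truncated DCT of a fixed-length cycle
#'
#' Computes the orthonormal DCT-II of a length-`L` cycle and keeps the first
#' `n` coefficients, the compact representation used on both sides of the
#' transfer model.
#'
#' @param values Numeric vector (a resampled, normalized cycle).
#' @param n Number of leading coefficients to keep (`n <= length(values)`).
#' @param modality Optional channel tag, `"ppg"` or `"ecg"`.
#' @return Object of class `dct_vector` with fields `coeffs`, `n`, `L`,
#'   `modality`.
#' @export
dct_forward <- function(values, n = length(values), modality = NULL) {
  L <- length(values)
  if (!is_count(n) || n < 1L || n > L) {
    stop_ppg2ecg("n must be an integer in [1, length(values)]",
                 "parameter_error")
  }
  structure(
    list(coeffs = dct_ii(values)[seq_len(n)], n = as.integer(n),
         L = as.integer(L), modality = modality),
    class = "dct_vector"
  )
}

#' Inverse DCT with zero padding
#'
#' Zero-pads a truncated coefficient vector back to the original cycle length
#' and applies the inverse orthonormal DCT-II, yielding the compressed
#' reconstruction of the cycle.
#'
#' @param v A `dct_vector` from [dct_forward()], or a plain numeric
#'   coefficient vector (then `L` must be given).
#' @param L Original cycle length (ignored when `v` is a `dct_vector`).
#' @return Numeric vector of length `L`.
#' @export
dct_inverse <- function(v, L = NULL) {
  if (inherits(v, "dct_vector")) {
    coeffs <- v$coeffs
    L <- v$L
  } else {
    coeffs <- as.numeric(v)
    if (is.null(L)) stop_ppg2ecg("L required for a bare coefficient vector",
                                 "parameter_error")
  }
  if (length(coeffs) > L) {
    stop_ppg2ecg("more coefficients than the cycle length", "parameter_error")
  }
  idct_ii(c(coeffs, rep(0, L - length(coeffs))))
}

#' Choose the DCT truncation order from a captured-energy threshold
#'
#' For each cycle the full orthonormal DCT is computed and the cumulative
#' energy fraction of the leading coefficients tracked; the returned order is
#' the smallest `n` whose mean captured-energy fraction across cycles reaches
#' `threshold`. Intended to be run on training cycles only, then held fixed.
#'
#' @param cycles A numeric matrix with one cycle per row, or a list of
#'   equal-length numeric vectors.
#' @param threshold Energy fraction in (0, 1]; default 0.9998.
#' @return Integer truncation order.
#' @export
select_coeff_count <- function(cycles, threshold = 0.9998) {
  if (is.list(cycles)) cycles <- do.call(rbind, cycles)
  if (!is.matrix(cycles) || nrow(cycles) < 1L) {
    stop_ppg2ecg("need at least one cycle", "parameter_error")
  }
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1) {
    stop_ppg2ecg("threshold must lie in (0, 1]", "parameter_error")
  }
  C2 <- t(apply(cycles, 1L, dct_ii))^2
  if (nrow(cycles) == 1L) C2 <- matrix(C2, nrow = 1L)
  E <- rowSums(C2)
  keep <- E > 0
  if (!any(keep)) {
    stop_ppg2ecg("all cycles have zero energy", "parameter_error")
  }
  frac <- apply(C2[keep, , drop = FALSE] / E[keep], 1L, cumsum)
  mean_frac <- rowMeans(matrix(frac, ncol = sum(keep)))
  # guard against cumulated rounding leaving the last entry below 1
  mean_frac[length(mean_frac)] <- 1
  as.integer(which(mean_frac >= threshold - 1e-12)[1L])
}

#' Coefficient-count selection policy
#'
#' Bundles the PPG and ECG truncation orders used by the transfer model.
#' `preset = "capnobase-paper"` gives the 11 (PPG) and 100 (ECG) coefficients
#' reported for 300 Hz, 8-minute CapnoBase recordings at the 99.98% energy
#' threshold; `preset = "auto"` defers the choice to the training data.
#'
#' @param n_ppg,n_ecg Explicit truncation orders (used when `preset = NULL`).
#' @param preset `"auto"`, `"capnobase-paper"`, or `NULL`.
#' @param threshold Energy fraction used when `preset = "auto"`.
#' @return Object of class `coeff_selection`.
#' @export
coeff_selection <- function(n_ppg = NULL, n_ecg = NULL, preset = NULL,
                            threshold = 0.9998) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("auto", "capnobase-paper"))
    if (preset == "capnobase-paper") {
      n_ppg <- 11L
      n_ecg <- 100L
    }
  }
  if (is.null(preset) || preset == "capnobase-paper") {
    if (!is_count(n_ppg) || !is_count(n_ecg) || n_ppg < 1L || n_ecg < 1L) {
      stop_ppg2ecg("n_ppg and n_ecg must be positive integers",
                   "parameter_error")
    }
  }
  structure(
    list(n_ppg = if (is.null(n_ppg)) NULL else as.integer(n_ppg),
         n_ecg = if (is.null(n_ecg)) NULL else as.integer(n_ecg),
         preset = preset, threshold = threshold),
    class = "coeff_selection"
  )
}
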