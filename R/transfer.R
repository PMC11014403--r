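# The closed-form ridge transfer function between PPG and ECG DCT coefficient
# spaces: f* = (X'X + gamma I)^{-1} X'Y, applied as Y_hat = X f*. The system
# is solved through a Cholesky factorization of the symmetric positive
# (semi-)definite normal matrix; the inverse is never formed explicitly.

#' Fit the ridge transfer function between coefficient spaces
#'
#' Solves the normal equations `(X'X + gamma I) f = X'Y` for the matrix `f`
#' mapping PPG DCT coefficients (columns of `X`) to ECG DCT coefficients
#' (columns of `Y`). No intercept and no column standardization: the model is
#' the literal closed form on normalized-cycle coefficients.
#'
#' @param X Numeric matrix, one training cycle's PPG coefficients per row.
#' @param Y Numeric matrix, matching ECG coefficients (same row count).
#' @param gamma Ridge penalty, `>= 0`. With `gamma = 0`, `X'X` must be
#'   invertible.
#' @return Object of class `transfer_model` with fields `f` (n_ppg x n_ecg),
#'   `gamma`, `n_ppg`, `n_ecg`.
#' @export
fit_ridge <- function(X, Y, gamma = 1.0) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) {
    stop_ppg2ecg("X and Y must have the same number of cycles (rows)",
                 "parameter_error")
  }
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma < 0) {
    stop_ppg2ecg("gamma must be a single number >= 0", "parameter_error")
  }
  A <- crossprod(X) + diag(gamma, ncol(X))
  B <- crossprod(X, Y)
  R <- tryCatch(chol(A), error = function(e) NULL)
  if (!is.null(R) && gamma == 0 && rcond(A) < 1e-12) R <- NULL
  if (is.null(R)) {
    stop_ppg2ecg(
      "normal matrix is singular; X'X is rank-deficient, use gamma > 0",
      "rank_error")
  }
  f <- backsolve(R, backsolve(R, B, transpose = TRUE))
  structure(list(f = f, gamma = gamma,
                 n_ppg = ncol(X), n_ecg = ncol(Y)),
            class = "transfer_model")
}

#' @export
print.transfer_model <- function(x, ...) {
  cat(sprintf("<transfer_model: %d PPG -> %d ECG coefficients, gamma=%g>\n",
              x$n_ppg, x$n_ecg, x$gamma))
  invisible(x)
}

#' Map PPG coefficients through a fitted transfer model
#'
#' @param object A `transfer_model`.
#' @param X Matrix of PPG coefficient rows (or a single coefficient vector).
#' @param ... Unused.
#' @return Matrix of predicted ECG coefficient rows.
#' @export
predict.transfer_model <- function(object, X, ...) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (ncol(X) != object$n_ppg) {
    stop_ppg2ecg("coefficient dimension does not match the model",
                 "parameter_error")
  }
  X %*% object$f
}

#' Reconstruct an ECG cycle from a PPG cycle
#'
#' The per-cycle inference path: truncated DCT of the normalized PPG cycle,
#' linear map through the transfer model, zero padding, inverse DCT. Returns
#' a normalized-amplitude ECG cycle estimate of the same fixed length.
#'
#' @param ppg_values Length-`L` normalized PPG cycle.
#' @param model A `transfer_model`.
#' @return Numeric vector of length `L`.
#' @export
reconstruct_cycle <- function(ppg_values, model) {
  x <- dct_forward(ppg_values, n = model$n_ppg, modality = "ppg")
  y <- drop(predict(model, x$coeffs))
  dct_inverse(y, L = length(ppg_values))
}

#' Choose the ridge penalty by inner validation
#'
#' Splits the training rows chronologically (first `train_frac` for fitting,
#' the rest for validation) and returns the penalty from a log-spaced grid
#' with the highest mean validation correlation between predicted and true
#' coefficient rows (compared in the reconstructed-cycle domain).
#'
#' @param X,Y Training coefficient matrices as in [fit_ridge()].
#' @param L Cycle length used to reconstruct validation cycles.
#' @param grid Candidate penalties; default `10^seq(-6, 3)`.
#' @param train_frac Fraction of rows used for fitting; default 0.8.
#' @return The selected penalty (a scalar from `grid`).
#' @export
select_gamma <- function(X, Y, L, grid = 10^seq(-6, 3), train_frac = 0.8) {
  n <- nrow(X)
  n_tr <- max(2L, floor(train_frac * n))
  if (n_tr >= n) stop_ppg2ecg("too few rows for an inner validation split",
                              "parameter_error")
  tr <- seq_len(n_tr)
  va <- (n_tr + 1L):n
  score <- vapply(grid, function(g) {
    m <- tryCatch(fit_ridge(X[tr, , drop = FALSE], Y[tr, , drop = FALSE], g),
                  error = function(e) NULL)
    if (is.null(m)) return(-Inf)
    Yh <- predict(m, X[va, , drop = FALSE])
    mean(vapply(seq_along(va), function(i) {
      r <- pearson(dct_inverse(Yh[i, ], L = L),
                   dct_inverse(Y[va[i], ], L = L))
      if (is.na(r)) 0 else r
    }, numeric(1)))
  }, numeric(1))
  grid[which.max(score)]
}
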