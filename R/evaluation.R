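# Evaluation: morphological (Pearson) and temporal (R-peak delay) scoring of
# reconstructions, the three train/test split schemes, and the concatenated-
# reconstruction correlation-decay experiment.

#' Resample and normalize cycle pairs to fixed-length matrices
#'
#' Applies [resample_linear()] and [normalize_minmax()] to both channels of
#' every pair, producing the row matrices consumed by the DCT/ridge stages.
#'
#' @param pairs List of `cycle_pair` objects.
#' @param L Fixed cycle length; default 300.
#' @return List with matrices `ppg`, `ecg` (one cycle per row) and a tibble
#'   `meta` (subject, mode, timing fields, per-cycle scale/offset).
#' @export
normalize_cycles <- function(pairs, L = 300L) {
  n <- length(pairs)
  if (n == 0L) stop_ppg2ecg("no cycles to normalize", "parameter_error")
  ppg <- matrix(0, n, L)
  ecg <- matrix(0, n, L)
  meta <- vector("list", n)
  for (i in seq_len(n)) {
    p <- pairs[[i]]
    np <- normalize_minmax(resample_linear(p$ppg_raw, L))
    ne <- normalize_minmax(resample_linear(p$ecg_raw, L))
    ppg[i, ] <- np$values
    ecg[i, ] <- ne$values
    meta[[i]] <- tibble::tibble(
      cycle = i, subject = p$subject_id, mode = p$mode,
      ppg_start_s = p$ppg_start_s, ppg_duration_s = p$ppg_duration_s,
      ecg_start_s = p$ecg_start_s, ecg_duration_s = p$ecg_duration_s,
      r_time_true_s = p$r_time_true_s,
      ecg_scale = ne$scale, ecg_offset = ne$offset)
  }
  list(ppg = ppg, ecg = ecg, meta = do.call(rbind, meta))
}

#' Pearson correlation between two cycles
#'
#' `cov(a, b) / (sd(a) sd(b))`. A constant input makes the correlation
#' undefined; such cases return `NA` and are excluded (but counted) by the
#' aggregation in [run_scheme()] rather than imputed.
#'
#' @param a,b Equal-length numeric vectors (length >= 2).
#' @return Correlation in `[-1, 1]`, or `NA` if either input is constant.
#' @export
pearson <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2L) {
    stop_ppg2ecg("inputs must have equal length >= 2", "parameter_error")
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Relative root-mean-squared error
#'
#' `||recon - gt||_2 / ||gt||_2`; optional morphology metric for comparison
#' with related reconstruction work.
#'
#' @param recon,gt Equal-length numeric vectors; `gt` must have nonzero norm.
#' @return Nonnegative scalar, or `NA` when `gt` has zero norm.
#' @export
rrmse <- function(recon, gt) {
  if (length(recon) != length(gt)) {
    stop_ppg2ecg("inputs must have equal length", "parameter_error")
  }
  den <- sqrt(sum(gt^2))
  if (den == 0) return(NA_real_)
  sqrt(sum((recon - gt)^2)) / den
}

#' Absolute R-peak delay of a reconstruction
#'
#' The reconstructed R location is the argmax of the normalized cycle
#' (optionally restricted to a fractional search window), placed in absolute
#' time on the *PPG* cycle's span - the only timing available when
#' reconstructing from PPG alone. In semantic mode this is what makes the
#' delay reflect the nulled pulse-arrival time; in direct mode the PPG and
#' ECG spans coincide.
#'
#' @param recon Length-`L` reconstructed cycle.
#' @param pair The `cycle_pair` the reconstruction belongs to (provides the
#'   timing fields and ground-truth R time).
#' @param search_frac Fractional window `c(lo, hi)` of the cycle searched for
#'   the R peak; default the whole cycle.
#' @return Absolute delay in seconds (>= 0).
#' @export
r_peak_delay <- function(recon, pair, search_frac = c(0, 1)) {
  if (is.null(pair$r_time_true_s) || is.na(pair$r_time_true_s)) {
    stop_ppg2ecg("cycle pair carries no ground-truth R time",
                 "evaluation_error")
  }
  L <- length(recon)
  idx <- seq_len(L)
  frac <- (idx - 1L) / L
  win <- which(frac >= search_frac[1L] & frac <= search_frac[2L])
  peak <- win[which.max(recon[win])]
  r_recon <- pair$ppg_start_s + (peak - 1L) / L * pair$ppg_duration_s
  abs(r_recon - pair$r_time_true_s)
}

# ---- split plans ----------------------------------------------------------

new_split_plan <- function(scheme, folds, metadata = list()) {
  structure(list(scheme = scheme, folds = folds, metadata = metadata),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan %s: %d folds>\n", x$scheme, length(x$folds)))
  invisible(x)
}

#' Sequential k-fold plan for a general model
#'
#' Cycles are kept stacked subject-by-subject in input order, without
#' shuffling, and cut into `k` contiguous near-equal folds; fold `i` is the
#' test set and the remainder the training set. Keeping subjects sequential
#' means train and test folds come overwhelmingly from different subjects,
#' so the scheme probes a general (non-personalized) model.
#'
#' @param pairs List of `cycle_pair` objects (stacked by subject).
#' @param k Number of folds (default 5).
#' @return A `split_plan` with scheme `"general-cv"`.
#' @export
build_general_cv <- function(pairs, k = 5L) {
  n <- length(pairs)
  if (!is_count(k) || k < 2L) stop_ppg2ecg("k must be an integer >= 2",
                                           "parameter_error")
  if (k > n) stop_ppg2ecg("more folds than cycles", "parameter_error")
  bounds <- floor(seq(0, n, length.out = k + 1L))
  folds <- lapply(seq_len(k), function(i) {
    test <- (bounds[i] + 1L):bounds[i + 1L]
    list(train = setdiff(seq_len(n), test), test = test)
  })
  new_split_plan("general-cv", folds, list(k = k))
}

#' Pooled sliding-window plan for a personalized model
#'
#' For one subject's cycles: each non-overlapping (by default) window of
#' `window` consecutive cycles contributes its first `round(train_frac *
#' window)` cycles to a pooled training set and the rest to a pooled test
#' set; a trailing partial window is dropped. One model per subject is then
#' fit on the pooled training set, which spreads both sets across the whole
#' recording so transient heart-rate excursions are represented in each.
#'
#' @param pairs One subject's `cycle_pair` list.
#' @param window Cycles per window (>= 5); default 20.
#' @param train_frac Fraction of each window used for training; default 0.8.
#' @param stride Step between window starts; default `window`.
#' @return A `split_plan` with scheme `"personalized-window"` and one fold.
#' @export
build_personalized_windows <- function(pairs, window = 20L, train_frac = 0.8,
                                       stride = window) {
  n <- length(pairs)
  if (!is_count(window) || window < 5L) {
    stop_ppg2ecg("window must be an integer >= 5", "parameter_error")
  }
  if (train_frac <= 0 || train_frac >= 1) {
    stop_ppg2ecg("train_frac must lie in (0, 1)", "parameter_error")
  }
  if (!is_count(stride) || stride < 1L) {
    stop_ppg2ecg("stride must be a positive integer", "parameter_error")
  }
  if (n < window) stop_ppg2ecg("fewer cycles than one window",
                               "parameter_error")
  n_train <- round(train_frac * window)
  train <- integer(0)
  test <- integer(0)
  start <- 1L
  while (start + window - 1L <= n) {
    w <- start:(start + window - 1L)
    train <- union(train, w[seq_len(n_train)])
    test <- union(test, w[(n_train + 1L):window])
    start <- start + stride
  }
  test <- setdiff(test, train)
  new_split_plan("personalized-window",
                 list(list(train = sort(train), test = sort(test))),
                 list(window = window, train_frac = train_frac,
                      stride = stride))
}

#' Leave-one-subject-out plan
#'
#' One fold per subject: that subject's cycles form the test set and all
#' other subjects' cycles the training set, so no personalization is
#' possible.
#'
#' @param pairs List of `cycle_pair` objects from at least 2 subjects.
#' @return A `split_plan` with scheme `"loso"`.
#' @export
build_loso <- function(pairs) {
  subjects <- vapply(pairs, function(p) p$subject_id, character(1))
  ids <- unique(subjects)
  if (length(ids) < 2L) stop_ppg2ecg("LOSO needs at least 2 subjects",
                                     "parameter_error")
  folds <- lapply(ids, function(id) {
    test <- which(subjects == id)
    list(train = which(subjects != id), test = test, subject = id)
  })
  new_split_plan("loso", folds, list(subjects = ids))
}

#' Build the split plan for an evaluation scheme
#'
#' Dispatches to the scheme-specific builder; for the personalized scheme on
#' a multi-subject cycle list, one pooled-window fold is built per subject.
#'
#' @param pairs List of `cycle_pair` objects.
#' @param scheme `"general-cv"`, `"personalized-window"`, or `"loso"`.
#' @param k Folds for `"general-cv"`.
#' @param window,train_frac,stride Parameters for `"personalized-window"`.
#' @return A `split_plan`.
#' @export
build_plan <- function(pairs, scheme = c("personalized-window", "general-cv",
                                         "loso"),
                       k = 5L, window = 20L, train_frac = 0.8,
                       stride = window) {
  scheme <- match.arg(scheme)
  if (scheme == "general-cv") return(build_general_cv(pairs, k))
  if (scheme == "loso") return(build_loso(pairs))
  subjects <- vapply(pairs, function(p) p$subject_id, character(1))
  folds <- list()
  for (id in unique(subjects)) {
    idx <- which(subjects == id)
    sub_plan <- build_personalized_windows(pairs[idx], window, train_frac,
                                           stride)
    f <- sub_plan$folds[[1L]]
    folds[[length(folds) + 1L]] <- list(train = idx[f$train],
                                        test = idx[f$test], subject = id)
  }
  new_split_plan("personalized-window", folds,
                 list(window = window, train_frac = train_frac,
                      stride = stride))
}

# ---- scheme runner --------------------------------------------------------

resolve_selection <- function(selection, train_ppg, train_ecg, L) {
  if (is.null(selection$preset) || selection$preset != "auto") {
    return(list(n_ppg = selection$n_ppg, n_ecg = selection$n_ecg))
  }
  list(n_ppg = min(L, select_coeff_count(train_ppg, selection$threshold)),
       n_ecg = min(L, select_coeff_count(train_ecg, selection$threshold)))
}

dct_rows <- function(mat, n) {
  out <- t(apply(mat, 1L, function(v) dct_ii(v)[seq_len(n)]))
  if (n == 1L) out <- matrix(out, ncol = 1L)
  out
}

#' Run an evaluation scheme over cycle pairs
#'
#' For every fold of the plan: the coefficient counts are chosen on the
#' training cycles only (unless fixed by the selection), the ridge transfer
#' function is fit on the training cycles, every test cycle is reconstructed
#' from its PPG coefficients, and the reconstruction is scored with the
#' Pearson correlation against the normalized true ECG cycle and the absolute
#' R-peak delay (plus relative RMSE when requested). Fully deterministic
#' given the inputs.
#'
#' @param plan A `split_plan` from [build_plan()].
#' @param pairs The `cycle_pair` list the plan indexes into.
#' @param L Fixed cycle length; default 300.
#' @param selection A [coeff_selection()]; default the data-driven 99.98%
#'   energy rule.
#' @param gamma Ridge penalty; default 1. Set `gamma_search = TRUE` to pick
#'   it per fold by inner validation on the training split.
#' @param gamma_search Logical; default `FALSE`.
#' @param with_rrmse Also compute relative RMSE per cycle; default `FALSE`.
#' @return Object of class `scheme_result`: `per_cycle` tibble (fold,
#'   subject, cycle, rho, r_delay_s, rrmse), `aggregates` (overall, per-fold
#'   and per-subject means), `selection_used`, `scheme`.
#' @export
run_scheme <- function(plan, pairs, L = 300L,
                       selection = coeff_selection(preset = "auto"),
                       gamma = 1.0, gamma_search = FALSE,
                       with_rrmse = FALSE) {
  norm <- normalize_cycles(pairs, L)
  rows <- list()
  sel_used <- list()
  for (fi in seq_along(plan$folds)) {
    fold <- plan$folds[[fi]]
    if (length(fold$train) < 2L) {
      warning(sprintf("fold %d skipped: fewer than 2 training cycles", fi))
      next
    }
    sel <- resolve_selection(selection,
                             norm$ppg[fold$train, , drop = FALSE],
                             norm$ecg[fold$train, , drop = FALSE], L)
    X <- dct_rows(norm$ppg[fold$train, , drop = FALSE], sel$n_ppg)
    Y <- dct_rows(norm$ecg[fold$train, , drop = FALSE], sel$n_ecg)
    g <- if (gamma_search) select_gamma(X, Y, L) else gamma
    model <- fit_ridge(X, Y, g)
    Xt <- dct_rows(norm$ppg[fold$test, , drop = FALSE], sel$n_ppg)
    Yh <- predict(model, Xt)
    sel_used[[fi]] <- c(sel, gamma = g)
    for (ti in seq_along(fold$test)) {
      ci <- fold$test[ti]
      recon <- dct_inverse(Yh[ti, ], L = L)
      gt <- norm$ecg[ci, ]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        fold = fi, subject = pairs[[ci]]$subject_id, cycle = ci,
        rho = pearson(recon, gt),
        r_delay_s = r_peak_delay(recon, pairs[[ci]]),
        rrmse = if (with_rrmse) rrmse(recon, gt) else NA_real_)
    }
  }
  if (length(rows) == 0L) {
    stop_ppg2ecg("no fold could be evaluated", "evaluation_error")
  }
  per_cycle <- do.call(rbind, rows)
  agg_of <- function(d) {
    tibble::tibble(n = nrow(d),
                   n_undefined_rho = sum(is.na(d$rho)),
                   mean_rho = mean(d$rho, na.rm = TRUE),
                   mean_r_delay_s = mean(d$r_delay_s),
                   mean_rrmse = mean(d$rrmse, na.rm = TRUE))
  }
  per_fold <- do.call(rbind, lapply(split(per_cycle, per_cycle$fold), agg_of))
  per_fold <- cbind(tibble::tibble(fold = as.integer(names(
    split(per_cycle, per_cycle$fold)))), per_fold)
  per_subject <- do.call(rbind, lapply(split(per_cycle, per_cycle$subject),
                                       agg_of))
  per_subject <- cbind(tibble::tibble(subject = names(
    split(per_cycle, per_cycle$subject))), per_subject)
  structure(list(per_cycle = per_cycle,
                 aggregates = list(overall = agg_of(per_cycle),
                                   per_fold = tibble::as_tibble(per_fold),
                                   per_subject = tibble::as_tibble(per_subject)),
                 selection_used = sel_used, scheme = plan$scheme),
            class = "scheme_result")
}

#' @export
print.scheme_result <- function(x, ...) {
  o <- x$aggregates$overall
  cat(sprintf("<scheme_result %s: %d cycles, mean rho=%.3f, mean R delay=%.3f s>\n",
              x$scheme, o$n, o$mean_rho, o$mean_r_delay_s))
  invisible(x)
}

# ---- concatenated-reconstruction decay ------------------------------------

#' Correlation of concatenated cycle reconstructions against the raw ECG
#'
#' Each reconstructed cycle is resampled back to its PPG cycle's duration
#' (the only duration known at inference time) and `k` consecutive
#' reconstructions are concatenated; the ground-truth span of equal length is
#' read from the raw ECG starting at the first cycle's ECG anchor (the
#' governing R peak in semantic mode, the shared cycle start in direct mode).
#' With semantic alignment the per-cycle pulse-arrival mismatch accumulates
#' into the concatenation, so the correlation decays as `k` grows.
#'
#' @param recons List of length-`L` reconstructed cycles, one per pair, in
#'   record order.
#' @param pairs The matching *consecutive* `cycle_pair` list.
#' @param record The `record_pair` providing the raw ECG channel.
#' @param ks Segment lengths in cycles, e.g. `c(1, 2, 4, 8, 16)`.
#' @param stride Step between segment start positions; default 1.
#' @return Tibble with columns `k`, `start`, `rho`.
#' @export
concat_correlation <- function(recons, pairs, record, ks = c(1, 2, 4, 8, 16),
                               stride = 1L) {
  n <- length(recons)
  if (n != length(pairs)) stop_ppg2ecg("recons and pairs differ in length",
                                       "parameter_error")
  if (n < max(ks)) stop_ppg2ecg("fewer cycles than max(ks)", "parameter_error")
  fs <- record$ppg$fs
  ecg <- record$ecg$samples
  n_samp <- vapply(pairs, function(p) {
    as.integer(max(2, round(p$ppg_duration_s * fs)))
  }, integer(1))
  stretched <- lapply(seq_len(n), function(i) {
    resample_linear(recons[[i]], n_samp[i])
  })
  anchor <- vapply(pairs, function(p) {
    if (p$mode == "semantic") p$r_time_true_s else p$ppg_start_s
  }, numeric(1))
  out <- list()
  for (k in ks) {
    for (j in seq(1L, n - k + 1L, by = stride)) {
      seg <- unlist(stretched[j:(j + k - 1L)], use.names = FALSE)
      i0 <- round((anchor[j] - record$t0) * fs) + 1L
      i1 <- i0 + length(seg) - 1L
      if (i0 < 1L || i1 > length(ecg)) next
      out[[length(out) + 1L]] <- tibble::tibble(
        k = k, start = j, rho = pearson(seg, ecg[i0:i1]))
    }
  }
  do.call(rbind, out)
}
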