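#' Stimulus design tensor for STRF fitting
#'
#' Builds the three-dimensional stimulus representation X[t, f, h]: the level
#' of tone f at chord t - h, for history lags h = 0 ... `history_steps` - 1
#' (lag 0 is the current chord). With 25-ms chords the default 16 steps span
#' 400 ms of stimulus history. Chords without a complete history are marked
#' incomplete and excluded from fitting.
#'
#' @param levels Chord-level matrix (n_chords x n_tones, dB SPL), e.g.
#'   `stim$levels` from [draw_chord_levels()].
#' @param history_steps Number of history lags (must be < n_chords).
#' @param step_s Chord/lag duration in seconds.
#' @return A 3-d array of class `design_tensor` with dimensions
#'   (time, frequency, history) and attributes `complete` (logical per row),
#'   `step_s` and `frequencies` (if `levels` has column names).
#' @export
build_design_tensor <- function(levels, history_steps = 16, step_s = 0.025) {
  levels <- as.matrix(levels)
  n_t <- nrow(levels)
  n_f <- ncol(levels)
  history_steps <- as.integer(history_steps)
  if (history_steps >= n_t) {
    stop(sprintf("history_steps = %d must be < n_chords = %d",
                 history_steps, n_t))
  }
  stopifnot(history_steps >= 1)
  X <- array(0, dim = c(n_t, n_f, history_steps))
  for (h in seq_len(history_steps)) {
    lag <- h - 1L
    X[(lag + 1L):n_t, , h] <- levels[1:(n_t - lag), ]
  }
  attr(X, "complete") <- seq_len(n_t) >= history_steps
  attr(X, "step_s") <- step_s
  fr <- suppressWarnings(as.numeric(colnames(levels)))
  if (!is.null(colnames(levels)) && !anyNA(fr)) {
    attr(X, "frequencies") <- fr
  }
  class(X) <- c("design_tensor", "array")
  X
}

# Rows usable for fitting: complete history, optionally dropping the initial
# adaptation period (in chords).
fit_rows_for <- function(X, exclude_initial = 0L) {
  which(attr(X, "complete") & seq_len(dim(X)[1]) > exclude_initial)
}

#' Fit a separable STRF by alternating least squares
#'
#' Estimates the linear stage of the encoding model: predicted response
#' `yhat_t = k0 + sum_{f,h} X[t,f,h] * k_f[f] * k_h[h]`, i.e. a rank-1
#' (separable) spectrotemporal receptive field, by minimising the
#' sum-of-squares error E. Each kernel is fitted in turn by least squares
#' with the other held fixed, repeated to convergence; E is non-increasing
#' across alternations. The scale ambiguity of the outer product is resolved
#' by normalising `k_h` to unit Euclidean norm with its largest-magnitude
#' element positive, so `k_f` carries the units (uV/dB).
#'
#' Stimulus levels are mean-centred before fitting (the scalar centre is
#' stored in the fitted object and applied again at prediction), which
#' conditions the regression without changing the model class.
#'
#' @param X A [build_design_tensor()] array.
#' @param y Response vector (uV per chord), length `dim(X)[1]`.
#' @param rows Rows used for fitting; defaults to all complete-history rows.
#' @param center Scalar centre subtracted from the stimulus levels, or `TRUE`
#'   to use the mean level over the fitted rows, or `FALSE`/0 for none.
#' @param tol Convergence tolerance on the relative change in E.
#' @param max_iter Maximum number of alternations.
#' @return A list with `strf` (a `separable_strf`: `k0`, `k_f`, `k_h`,
#'   `center`, `step_s`, `frequencies`) and `report` (`E`, `n_iter`,
#'   `converged`).
#' @export
fit_separable_strf <- function(X, y, rows = NULL, center = TRUE,
                               tol = 1e-6, max_iter = 100) {
  stopifnot(inherits(X, "design_tensor"), length(y) == dim(X)[1])
  if (is.null(rows)) rows <- fit_rows_for(X)
  d <- dim(X)
  n_f <- d[2]
  n_h <- d[3]
  if (length(rows) < n_f + n_h + 1) {
    stop("fewer fitting rows than free parameters")
  }
  Xr <- array(X[rows, , , drop = FALSE], dim = c(length(rows), n_f, n_h))
  yr <- y[rows]
  mu <- if (isTRUE(center)) mean(Xr) else if (isFALSE(center)) 0 else center
  Xr <- Xr - mu
  n_r <- length(rows)

  # k_h initialised on the earliest lags; deterministic
  kh <- c(rep(1, min(3L, n_h)), rep(0, max(0L, n_h - 3L)))
  kh <- kh / sqrt(sum(kh^2))
  kf <- rep(0, n_f)
  k0 <- mean(yr)
  e_prev <- Inf
  converged <- FALSE
  iter <- 0L
  Xmat_f <- matrix(Xr, nrow = n_r * n_f, ncol = n_h)     # for contracting h
  Xperm <- aperm(Xr, c(1, 3, 2))
  Xmat_h <- matrix(Xperm, nrow = n_r * n_h, ncol = n_f)  # for contracting f
  for (iter in seq_len(max_iter)) {
    # contract over history: S_f[t, f] = sum_h X[t,f,h] kh[h]
    Sf <- matrix(Xmat_f %*% kh, nrow = n_r, ncol = n_f)
    fit_f <- stats::lm.fit(cbind(1, Sf), yr)
    cf <- fit_f$coefficients
    cf[is.na(cf)] <- 0
    k0 <- cf[1]
    kf <- cf[-1]
    # contract over frequency: S_h[t, h] = sum_f X[t,f,h] kf[f]
    Sh <- matrix(Xmat_h %*% kf, nrow = n_r, ncol = n_h)
    fit_h <- stats::lm.fit(cbind(1, Sh), yr)
    ch <- fit_h$coefficients
    ch[is.na(ch)] <- 0
    k0 <- ch[1]
    kh_new <- ch[-1]
    nrm <- sqrt(sum(kh_new^2))
    if (nrm > 0) {
      sgn <- sign(kh_new[which.max(abs(kh_new))])
      kh <- kh_new * sgn / nrm
      kf <- kf * nrm * sgn
    } else {
      kh <- kh_new
      kf <- rep(0, n_f)
    }
    e <- sum((yr - (k0 + matrix(Xmat_f %*% kh, n_r, n_f) %*% kf))^2)
    if (e <= 1e-12 * max(sum(yr^2), .Machine$double.eps)) {
      # error at numerical zero (noiseless data): relative-change tests
      # are meaningless at machine precision
      e_prev <- e
      converged <- TRUE
      break
    }
    if (is.finite(e_prev) && e_prev > 0 &&
        abs(e_prev - e) / e_prev < tol) {
      e_prev <- e
      converged <- TRUE
      break
    }
    e_prev <- e
  }
  strf <- list(
    k0 = unname(k0), k_f = unname(kf), k_h = unname(kh), center = mu,
    step_s = attr(X, "step_s"), frequencies = attr(X, "frequencies")
  )
  class(strf) <- "separable_strf"
  list(
    strf = strf,
    report = list(E = unname(e_prev), n_iter = iter, converged = converged)
  )
}

#' Full STRF kernel as the outer product of the fitted kernels
#'
#' @param strf A `separable_strf`.
#' @return Matrix `k_fh` (frequency x history), uV/dB.
#' @export
strf_kernel <- function(strf) {
  outer(strf$k_f, strf$k_h)
}

#' Linear drive predicted by a separable STRF
#'
#' Evaluates `z_t = k0 + sum_{f,h} (X[t,f,h] - center) * k_fh[f,h]`, the STRF
#' output fed to the output nonlinearity.
#'
#' @param object A `separable_strf`.
#' @param X A [build_design_tensor()] array with matching frequency and
#'   history dimensions.
#' @param ... Unused.
#' @return Numeric vector `z_t`, one value per chord.
#' @export
predict.separable_strf <- function(object, X, ...) {
  d <- dim(X)
  if (d[2] != length(object$k_f) || d[3] != length(object$k_h)) {
    stop("design tensor dimensions do not match the STRF kernels")
  }
  n_t <- d[1]
  Xc <- array(X, dim = d) - object$center
  Sf <- matrix(matrix(Xc, nrow = n_t * d[2], ncol = d[3]) %*% object$k_h,
               nrow = n_t, ncol = d[2])
  as.numeric(object$k0 + Sf %*% object$k_f)
}

#' @export
print.separable_strf <- function(x, ...) {
  cat(sprintf(
    "<separable_strf> %d freq bins x %d lags (%.0f ms history), k0 = %.3g\n",
    length(x$k_f), length(x$k_h), 1000 * length(x$k_h) * x$step_s, x$k0
  ))
  invisible(x)
}

#' Cross-validated predictive power of an STRF
#'
#' Fits the separable STRF to the first `fit_fraction` of the usable chords
#' (a contiguous block, avoiding temporal leakage through the stimulus
#' history) and computes the Pearson correlation between predicted and
#' observed responses on the remaining held-out block. A unit is deemed
#' predictive when the test correlation exceeds `cc_threshold` (default
#' 0.04, a value chosen to lie outside the null distribution of chance
#' correlations; see [null_cc_threshold()]).
#'
#' @inheritParams fit_separable_strf
#' @param fit_fraction Fraction of usable rows used for fitting.
#' @param cc_threshold Predictive screening threshold on the test CC.
#' @param ... Passed to [fit_separable_strf()].
#' @return A list: `cc_test`, `predictive`, `E`, `strf`, `test_rows`. If the
#'   held-out responses have zero variance the CC is `NA` and the unit is
#'   marked non-predictive (with a warning).
#' @export
cross_validated_cc <- function(X, y, rows = NULL, fit_fraction = 0.9,
                               cc_threshold = 0.04, ...) {
  if (is.null(rows)) rows <- fit_rows_for(X)
  n <- length(rows)
  n_fit <- floor(fit_fraction * n)
  stopifnot(n_fit >= 1, n_fit < n)
  fit_rows <- rows[seq_len(n_fit)]
  test_rows <- rows[(n_fit + 1L):n]
  fit <- fit_separable_strf(X, y, rows = fit_rows, ...)
  pred <- predict(fit$strf, X)[test_rows]
  obs <- y[test_rows]
  if (stats::sd(obs) == 0 || stats::sd(pred) == 0) {
    warning("zero-variance test responses or predictions; CC undefined")
    cc <- NA_real_
  } else {
    cc <- stats::cor(pred, obs)
  }
  list(
    cc_test = cc,
    predictive = isTRUE(cc > cc_threshold),
    E = fit$report$E,
    strf = fit$strf,
    test_rows = test_rows
  )
}

#' Cross-condition predictive power
#'
#' Evaluates an STRF trained on one contrast condition against held-out data
#' from the other condition: the Pearson correlation between its predictions
#' and the observed responses on the final `test_fraction` of the other
#' condition's usable chords. Calling it with the training condition's own
#' data reproduces [cross_validated_cc()]'s test correlation.
#'
#' @param strf A fitted `separable_strf` (trained on condition A).
#' @param X_b,y_b Design tensor and responses of condition B.
#' @param rows Usable rows of condition B (default: complete-history rows).
#' @param test_fraction Final fraction of `rows` used for evaluation.
#' @param cc_threshold Screening threshold.
#' @return As [cross_validated_cc()] (without refitting).
#' @export
cross_condition_cc <- function(strf, X_b, y_b, rows = NULL,
                               test_fraction = 0.1, cc_threshold = 0.04) {
  if (is.null(rows)) rows <- fit_rows_for(X_b)
  n <- length(rows)
  n_test <- max(1L, ceiling(test_fraction * n))
  test_rows <- rows[(n - n_test + 1L):n]
  pred <- predict(strf, X_b)[test_rows]
  obs <- y_b[test_rows]
  if (stats::sd(obs) == 0 || stats::sd(pred) == 0) {
    warning("zero-variance test responses or predictions; CC undefined")
    cc <- NA_real_
  } else {
    cc <- stats::cor(pred, obs)
  }
  list(cc_test = cc, predictive = isTRUE(cc > cc_threshold),
       test_rows = test_rows)
}

#' Null distribution threshold for the predictive screen
#'
#' Re-derives a chance level for the test correlation by circularly shifting
#' the response vector relative to the stimulus and recomputing the
#' cross-validated CC, returning the requested quantile of the null
#' distribution. Provided so the 0.04 default can be checked against any
#' particular stimulus/response geometry.
#'
#' @inheritParams cross_validated_cc
#' @param n_shifts Number of circular shifts.
#' @param probs Quantile of the null |CC| distribution to return.
#' @param seed Seed for the shift offsets.
#' @return The null quantile (numeric), with the null CCs as attribute
#'   `null_cc`.
#' @export
null_cc_threshold <- function(X, y, n_shifts = 50, probs = 0.99, seed = 1,
                              ...) {
  n <- length(y)
  offs <- with_seed(seed, sample(seq(50L, n - 50L), n_shifts, replace = TRUE))
  ccs <- vapply(offs, function(o) {
    ys <- y[((seq_len(n) - 1 + o) %% n) + 1]
    r <- suppressWarnings(cross_validated_cc(X, ys, ...))
    if (is.na(r$cc_test)) 0 else r$cc_test
  }, numeric(1))
  out <- unname(stats::quantile(abs(ccs), probs))
  attr(out, "null_cc") <- ccs
  out
}

#' Tuning metrics of a fitted STRF
#'
#' Summarises the spectral and temporal tuning of a separable STRF:
#' \itemize{
#'   \item `bf`: best frequency, the grid frequency of the largest frequency-
#'     kernel coefficient (for multi-peaked kernels this is the peak with the
#'     largest response);
#'   \item `bandwidth`: width of the frequency kernel around that peak at
#'     half its amplitude, in octaves, with linear interpolation between bins
#'     (clipped at the grid edges when the half-maximum is not crossed);
#'   \item `integration_time`: width at 50% of the peak history-kernel
#'     coefficient found within the first 100 ms of stimulus history, in ms;
#'   \item `largest_coeff`: the largest coefficient of the full kernel
#'     `k_fh`, in uV/dB.
#' }
#'
#' @param strf A `separable_strf`.
#' @param grid The [make_tone_grid()] the stimulus was built on.
#' @return A list with `bf` (Hz), `bandwidth` (octaves), `integration_time`
#'   (ms) and `largest_coeff` (uV/dB).
#' @export
tuning_metrics <- function(strf, grid) {
  kf <- strf$k_f
  kh <- strf$k_h
  if (all(kf == 0) || all(kh == 0)) {
    stop("degenerate (all-zero) kernel: tuning metrics undefined")
  }
  stopifnot(length(kf) == length(grid$frequencies))
  i_pk <- which.max(kf)
  bf <- grid$frequencies[i_pk]
  bw_bins <- half_max_width(kf, i_pk)
  bandwidth <- bw_bins * grid$spacing_octaves
  step_ms <- 1000 * strf$step_s
  early <- which((seq_along(kh) - 1) * step_ms < 100)
  h_pk <- early[which.max(kh[early])]
  it_ms <- half_max_width(kh, h_pk) * step_ms
  kfh <- strf_kernel(strf)
  list(bf = bf, bandwidth = bandwidth, integration_time = it_ms,
       largest_coeff = max(kfh))
}

# Width of a sampled curve around peak index i_pk at half the peak value,
# in bin units, using linear interpolation between samples; clipped at the
# array edges when the curve never falls below half-max.
half_max_width <- function(v, i_pk) {
  half <- v[i_pk] / 2
  n <- length(v)
  left <- 1
  if (i_pk > 1L) {
    for (i in seq(i_pk, 2L)) {
      if (v[i - 1] < half) {
        left <- (i - 1) + (half - v[i - 1]) / (v[i] - v[i - 1])
        break
      }
    }
  }
  right <- n
  if (i_pk < n) {
    for (i in seq(i_pk, n - 1L)) {
      if (v[i + 1] < half) {
        right <- i + (v[i] - half) / (v[i] - v[i + 1])
        break
      }
    }
  }
  right - left
}
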