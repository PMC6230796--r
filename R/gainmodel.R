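#' Sigmoidal output nonlinearity parameters
#'
#' The static output nonlinearity of the encoding model,
#' `F(z) = a + b / (1 + exp(-(z - c) / d))`, maps the STRF's linear drive z
#' onto the response. `a` is the baseline (y-offset, uV), `b` the response
#' range (uV), `c` the threshold (x-offset, in z units) and `d` the inverse
#' slope (z units); the neuron's gain is `1/d`. The curve rectifies the
#' drive and captures both response threshold and saturation.
#'
#' @param a,b,c,d Parameters; `b > 0` and `d > 0` are required so that F is
#'   increasing with range `[a, a + b]`.
#' @return A `sigmoid_params` object.
#' @export
sigmoid_params <- function(a, b, c, d) {
  stopifnot(is.finite(a), is.finite(b), is.finite(c), is.finite(d))
  if (b <= 0) stop("sigmoid range b must be > 0")
  if (d <= 0) stop("sigmoid inverse slope d must be > 0")
  p <- list(a = a, b = b, c = c, d = d)
  class(p) <- "sigmoid_params"
  p
}

#' @export
print.sigmoid_params <- function(x, ...) {
  cat(sprintf(
    "<sigmoid_params> a = %.4g, b = %.4g, c = %.4g, d = %.4g (gain 1/d = %.4g)\n",
    x$a, x$b, x$c, x$d, 1 / x$d
  ))
  invisible(x)
}

#' Evaluate the sigmoid nonlinearity
#'
#' @param z Linear drive values.
#' @param p A [sigmoid_params()] object.
#' @return `a + b / (1 + exp(-(z - c) / d))`.
#' @export
sigmoid_eval <- function(z, p) {
  p$a + p$b / (1 + exp(-(z - p$c) / p$d))
}

# Sum-of-squares objective for a parameter vector c(a, b, c, d).
sigmoid_sse <- function(par, z, y) {
  f <- par[1] + par[2] / (1 + exp(-(z - par[3]) / par[4]))
  sum((y - f)^2)
}

# Deterministic jittered starts around an initial parameter vector. One
# start is anchored at the ordinary least-squares line through (z, y): a
# sigmoid with midpoint slope b0/(4 d) equal to the fitted slope, matching
# the line at the mean drive. This anchors the fit in the near-linear
# regime, where only the slope is well determined.
sigmoid_starts <- function(z, y) {
  a0 <- min(y)
  b0 <- max(diff(range(y)), 1e-6)
  c0 <- stats::median(z)
  d0 <- max(stats::sd(z) / 2, 1e-6)
  s <- stats::sd(z)
  starts <- rbind(
    c(a0, b0, c0, d0),
    c(a0, b0, c0 + 0.5 * s, d0),
    c(a0, b0, c0 - 0.5 * s, d0),
    c(a0, b0, c0, d0 * 2),
    c(a0, 2 * b0, c0, d0 / 2)
  )
  ls <- stats::lm.fit(cbind(1, z), y)$coefficients
  anch <- sigmoid_anchor(ls[1], ls[2], a0, b0, mean(z))
  if (!is.null(anch)) starts <- rbind(starts, anch)
  starts
}

# Sigmoid parameters whose tangent at the mean drive reproduces a fitted
# line y = intercept + slope * z, given baseline a0 and range b0.
sigmoid_anchor <- function(intercept, slope, a0, b0, z_bar) {
  if (!is.finite(slope) || slope == 0) {
    return(NULL)
  }
  d0 <- b0 / (4 * abs(slope))
  c0 <- z_bar - 4 * d0 * (intercept + slope * z_bar - a0 - b0 / 2) / b0
  c(a0, b0, c0, d0)
}

#' Fit the sigmoidal output nonlinearity
#'
#' Minimises the sum-of-squares error between observed responses and
#' `F(z) = a + b / (1 + exp(-(z - c) / d))` by bounded quasi-Newton descent
#' (L-BFGS-B), from a deterministic set of jittered initialisations (best
#' objective kept), so repeated fits of the same data give the same answer.
#' Parameters can be held fixed via `free`, e.g. to refit only threshold and
#' gain with baseline and range pinned.
#'
#' @param z Linear drive (STRF output) per chord; must have positive
#'   variance.
#' @param y Observed responses (uV), same length as `z`. At least 50 pairs
#'   are required.
#' @param free Character vector naming the free parameters (subset of
#'   `c("a", "b", "c", "d")`).
#' @param fixed Named list of values for the non-free parameters (defaults
#'   to their initialisation values if omitted).
#' @return A [sigmoid_params()] with attributes `sse` (objective at the
#'   optimum) and `boundary` (`TRUE` when `b` collapsed to its lower bound,
#'   as for constant responses).
#' @export
fit_output_nonlinearity <- function(z, y, free = c("a", "b", "c", "d"),
                                    fixed = list()) {
  stopifnot(length(z) == length(y), length(z) >= 50)
  if (stats::sd(z) == 0) stop("degenerate drive: z has zero variance")
  free <- match.arg(free, c("a", "b", "c", "d"), several.ok = TRUE)
  names_all <- c("a", "b", "c", "d")
  b_floor <- max(1e-9, 1e-9 * diff(range(y)))
  # a transition narrower than ~1% of the drive spread is unresolvable from
  # (z, y) data and signals an overfit step; keep d away from it
  lower <- c(-Inf, b_floor, -Inf, stats::sd(z) / 100)
  starts <- sigmoid_starts(z, y)
  for (nm in names(fixed)) {
    starts[, match(nm, names_all)] <- fixed[[nm]]
  }
  idx_free <- match(free, names_all)
  best <- NULL
  for (si in seq_len(nrow(starts))) {
    full0 <- starts[si, ]
    fn <- function(par) {
      full <- full0
      full[idx_free] <- par
      sigmoid_sse(full, z, y)
    }
    res <- tryCatch(
      stats::optim(full0[idx_free], fn, method = "L-BFGS-B",
                   lower = lower[idx_free],
                   control = list(maxit = 500)),
      error = function(e) NULL
    )
    if (!is.null(res) && (is.null(best) || res$value < best$value)) {
      best <- res
      best$full <- full0
      best$full[idx_free] <- res$par
    }
  }
  if (is.null(best)) stop("sigmoid fit failed from all starts")
  pb <- unname(best$full)
  p <- sigmoid_params(pb[1], max(pb[2], b_floor), pb[3], max(pb[4], 1e-12))
  attr(p, "sse") <- best$value
  # boundary: the range collapsed, or the fitted curve is effectively flat
  # over the observed drive (as for constant responses)
  eff <- abs(diff(sigmoid_eval(range(z), p)))
  attr(p, "boundary") <- pb[2] <= b_floor * 1.01 ||
    eff < 1e-6 * max(stats::sd(y), p$b * 1e-3)
  p
}

#' Fit the dual-condition contrast gain model
#'
#' The central model of the analysis: one separable STRF fitted jointly to
#' the responses from both contrast conditions, followed by a sigmoidal
#' output nonlinearity whose baseline `a` and range `b` are shared between
#' conditions while threshold `c` and inverse slope `d` are condition
#' specific. Contrast gain control appears as `d_high > d_low` (lower gain
#' `1/d` under high contrast). Stimulus levels are mean-centred per
#' condition before the joint STRF fit.
#'
#' The per-condition drives fed to the sigmoid stage are computed by
#' cross-fitting: the pooled chords are split into `n_folds` interleaved
#' folds, a pooled STRF is fitted to each fold's complement, and each
#' chord's drive is the projection of its (centred) stimulus onto the
#' held-out unit-norm kernel direction. Computing the drive from a kernel
#' never trained on that chord's response removes the regression dilution
#' that reusing in-sample predictions would cause, and because the DRC
#' levels are white, projecting both conditions onto the same direction
#' leaves the between-condition slope ratio - the gain ratio - unbiased by
#' kernel estimation error. The reported STRF itself is fitted on all
#' pooled chords.
#'
#' Fully free per-condition sigmoid fits are also computed (components
#' `free_low`, `free_high`); these provide the baseline-change summary,
#' since baseline differences are small enough to be held shared in the
#' final model.
#'
#' @param X_low,X_high Design tensors of the two conditions (same frequency
#'   and history dimensions).
#' @param y_low,y_high Binned responses of the two conditions.
#' @param rows_low,rows_high Fitting rows per condition (default: complete-
#'   history rows).
#' @param n_folds Number of interleaved cross-fitting folds for the drive
#'   computation (>= 2).
#' @param ... Passed to [fit_separable_strf()].
#' @return A `dual_condition_fit`: list with `strf`, shared `a`, `b`,
#'   per-condition `c_low`, `d_low`, `c_high`, `d_high`, `fit_error`
#'   (summed SSE of the joint sigmoid stage), per-condition drives `z_low`,
#'   `z_high`, and free fits `free_low`, `free_high`.
#' @export
fit_dual_condition_model <- function(X_low, y_low, X_high, y_high,
                                     rows_low = NULL, rows_high = NULL,
                                     n_folds = 2, ...) {
  if (is.null(rows_low)) rows_low <- fit_rows_for(X_low)
  if (is.null(rows_high)) rows_high <- fit_rows_for(X_high)
  d_l <- dim(X_low)
  d_h <- dim(X_high)
  stopifnot(d_l[2] == d_h[2], d_l[3] == d_h[3], n_folds >= 2)
  n_l <- length(rows_low)
  n_h <- length(rows_high)
  mu_l <- mean(X_low[rows_low, , ])
  mu_h <- mean(X_high[rows_high, , ])

  pooled_fit <- function(rl, rh) {
    nl <- length(rl)
    nh <- length(rh)
    Xc <- array(0, dim = c(nl + nh, d_l[2], d_l[3]))
    Xc[seq_len(nl), , ] <- X_low[rl, , ] - mu_l
    Xc[nl + seq_len(nh), , ] <- X_high[rh, , ] - mu_h
    attr(Xc, "complete") <- rep(TRUE, nl + nh)
    attr(Xc, "step_s") <- attr(X_low, "step_s")
    attr(Xc, "frequencies") <- attr(X_low, "frequencies")
    class(Xc) <- c("design_tensor", "array")
    fit_separable_strf(Xc, c(y_low[rl], y_high[rh]),
                       rows = seq_len(nl + nh), center = FALSE, ...)
  }

  sfit <- pooled_fit(rows_low, rows_high)
  strf <- sfit$strf
  k_full <- as.numeric(strf_kernel(strf))

  # cross-fitted drives: project each fold's stimuli onto the held-out
  # kernel direction (unit Frobenius norm, sign-aligned with the full fit)
  M_l <- matrix(X_low[rows_low, , ] - mu_l, nrow = n_l)
  M_h <- matrix(X_high[rows_high, , ] - mu_h, nrow = n_h)
  folds_l <- rep(seq_len(n_folds), length.out = n_l)
  folds_h <- rep(seq_len(n_folds), length.out = n_h)
  z_low <- numeric(n_l)
  z_high <- numeric(n_h)
  for (k in seq_len(n_folds)) {
    f_k <- pooled_fit(rows_low[folds_l != k], rows_high[folds_h != k])
    u <- as.numeric(strf_kernel(f_k$strf))
    nrm <- sqrt(sum(u^2))
    if (nrm == 0) next
    u <- u / nrm
    if (sum(u * k_full) < 0) u <- -u
    z_low[folds_l == k] <- M_l[folds_l == k, , drop = FALSE] %*% u
    z_high[folds_h == k] <- M_h[folds_h == k, , drop = FALSE] %*% u
  }

  yl <- y_low[rows_low]
  yh <- y_high[rows_high]
  if (stats::sd(z_low) == 0 || stats::sd(z_high) == 0) {
    stop("degenerate cross-fitted drive (zero variance)")
  }
  free_low <- fit_output_nonlinearity(z_low, yl)
  free_high <- fit_output_nonlinearity(z_high, yh)

  # joint objective over (a, b, c_l, d_l, c_h, d_h)
  fn <- function(par) {
    sigmoid_sse(c(par[1], par[2], par[3], par[4]), z_low, yl) +
      sigmoid_sse(c(par[1], par[2], par[5], par[6]), z_high, yh)
  }
  b_floor <- max(1e-9, 1e-9 * diff(range(c(yl, yh))))
  # resolvable-transition floor, as in fit_output_nonlinearity()
  d_floor_l <- stats::sd(z_low) / 100
  d_floor_h <- stats::sd(z_high) / 100
  lower <- c(-Inf, b_floor, -Inf, d_floor_l, -Inf, d_floor_h)
  a0 <- min(c(yl, yh))
  b0 <- max(diff(range(c(yl, yh))), 1e-6)
  ls_l <- stats::lm.fit(cbind(1, z_low), yl)$coefficients
  ls_h <- stats::lm.fit(cbind(1, z_high), yh)$coefficients
  an_l <- sigmoid_anchor(ls_l[1], ls_l[2], a0, b0, mean(z_low))
  an_h <- sigmoid_anchor(ls_h[1], ls_h[2], a0, b0, mean(z_high))
  p0 <- c(
    mean(c(free_low$a, free_high$a)), mean(c(free_low$b, free_high$b)),
    free_low$c, free_low$d, free_high$c, free_high$d
  )
  starts <- rbind(
    p0,
    p0 * c(1, 1, 1, 0.5, 1, 0.5),
    p0 * c(1, 1, 1, 2, 1, 2),
    c(p0[1], p0[2], stats::median(z_low), stats::sd(z_low) / 2,
      stats::median(z_high), stats::sd(z_high) / 2)
  )
  if (!is.null(an_l) && !is.null(an_h)) {
    starts <- rbind(starts, c(a0, b0, an_l[3], an_l[4], an_h[3], an_h[4]))
  }
  best <- NULL
  for (si in seq_len(nrow(starts))) {
    res <- tryCatch(
      stats::optim(starts[si, ], fn, method = "L-BFGS-B", lower = lower,
                   control = list(maxit = 1000)),
      error = function(e) NULL
    )
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best)) stop("dual-condition sigmoid fit failed")
  pb <- unname(best$par)
  fit <- list(
    strf = strf, a = pb[1], b = pb[2],
    c_low = pb[3], d_low = pb[4], c_high = pb[5], d_high = pb[6],
    fit_error = best$value,
    center_low = mu_l, center_high = mu_h,
    z_low = z_low, z_high = z_high,
    free_low = free_low, free_high = free_high,
    strf_report = sfit$report
  )
  class(fit) <- "dual_condition_fit"
  fit
}

#' @export
print.dual_condition_fit <- function(x, ...) {
  s <- summarize_changes(x)
  cat(sprintf(
    paste0("<dual_condition_fit> gain 1/d: %.3g -> %.3g (%+.1f%%), ",
           "threshold c: %.3g -> %.3g (%+.1f%%)\n"),
    1 / x$d_low, 1 / x$d_high, s$gain_change_pct,
    x$c_low, x$c_high, s$threshold_change_pct
  ))
  invisible(x)
}

#' Contrast-dependent parameter changes of a fitted unit
#'
#' Percentage changes of the nonlinearity parameters under high- relative to
#' low-contrast stimulation. Gain change is
#' `100 * ((1/d_high) - (1/d_low)) / (1/d_low)`; negative values indicate a
#' compensatory gain reduction under high contrast. Threshold change is the
#' percentage change of `c`. Gain and threshold changes come from the
#' shared-(a, b) dual fit; the baseline change comes from the per-condition
#' fully free fits, where `a` is unconstrained.
#'
#' @param fit A [fit_dual_condition_model()] result.
#' @param free_low,free_high Optional per-condition free [sigmoid_params()]
#'   overriding those stored in `fit`.
#' @return List with `gain_change_pct`, `threshold_change_pct`,
#'   `baseline_change_pct`, plus the underlying `gain_low`, `gain_high`.
#' @export
summarize_changes <- function(fit, free_low = fit$free_low,
                              free_high = fit$free_high) {
  g_l <- 1 / fit$d_low
  g_h <- 1 / fit$d_high
  list(
    gain_change_pct = 100 * (g_h - g_l) / g_l,
    threshold_change_pct = 100 * (fit$c_high - fit$c_low) / abs(fit$c_low),
    baseline_change_pct =
      100 * (free_high$a - free_low$a) / abs(free_low$a),
    gain_low = g_l, gain_high = g_h
  )
}
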