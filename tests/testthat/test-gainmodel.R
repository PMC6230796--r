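test_that("sigmoid evaluation follows the four-parameter form", {
  p <- sigmoid_params(a = 2, b = 10, c = 1, d = 0.5)
  expect_equal(sigmoid_eval(1, p), 2 + 5) # midpoint
  expect_equal(sigmoid_eval(1e6, p), 12) # upper asymptote
  expect_equal(sigmoid_eval(-1e6, p), 2) # lower asymptote
  # slope at the midpoint is b / (4 d)
  eps <- 1e-6
  slope <- (sigmoid_eval(1 + eps, p) - sigmoid_eval(1 - eps, p)) / (2 * eps)
  expect_equal(slope, 10 / (4 * 0.5), tolerance = 1e-6)

  expect_error(sigmoid_params(0, -1, 0, 1), "b must be")
  expect_error(sigmoid_params(0, 1, 0, 0), "d must be")
})

test_that("sigmoid fitting recovers exact and noisy parameters", {
  truth <- sigmoid_params(a = 2, b = 10, c = 1, d = 2)
  z <- with_seed_test(1, rnorm(400, 0, 5))
  y <- sigmoid_eval(z, truth)
  fit <- fit_output_nonlinearity(z, y)
  for (nm in c("a", "b", "c", "d")) {
    expect_equal(fit[[nm]], truth[[nm]], tolerance = 1e-4)
  }

  # constant response: range collapses to the boundary, baseline = mean
  yc <- rep(4, 100)
  zc <- with_seed_test(2, rnorm(100, 0, 3))
  fitc <- fit_output_nonlinearity(zc, yc)
  expect_true(attr(fitc, "boundary"))
  expect_equal(sigmoid_eval(0, fitc), 4, tolerance = 1e-3)

  expect_error(fit_output_nonlinearity(rep(1, 100), rnorm(100)),
               "zero variance")

  # 5% noise, n = 1600: gain recovered within 5% in every one of 20 seeds
  z2 <- with_seed_test(3, rnorm(1600, 0, 5))
  rel_err <- vapply(1:20, function(i) {
    y2 <- sigmoid_eval(z2, truth) +
      with_seed_test(10 + i, rnorm(1600, 0, 0.05 * truth$b))
    f <- fit_output_nonlinearity(z2, y2)
    abs(1 / f$d - 1 / truth$d) / (1 / truth$d)
  }, numeric(1))
  expect_lt(median(rel_err), 0.05)
  expect_lt(max(rel_err), 0.15)
})

test_that("gain estimates are invariant to affine rescaling of the drive", {
  truth <- sigmoid_params(a = 1, b = 8, c = 0.5, d = 1.5)
  z <- with_seed_test(5, rnorm(300, 0, 4))
  y <- sigmoid_eval(z, truth)
  f1 <- fit_output_nonlinearity(z, y)
  f2 <- fit_output_nonlinearity(2 * z + 3, y)
  expect_equal(f2$d, 2 * f1$d, tolerance = 1e-3)
  expect_equal(f2$c, 2 * f1$c + 3, tolerance = 1e-3)
  expect_equal(f2$a, f1$a, tolerance = 1e-4)
  expect_equal(f2$b, f1$b, tolerance = 1e-4)
})

test_that("change summaries follow the printed percentage conventions", {
  fit <- list(d_low = 0.5, d_high = 1, c_low = 1, c_high = 1.006,
              free_low = list(a = 2), free_high = list(a = 2.1))
  s <- summarize_changes(fit)
  expect_equal(s$gain_change_pct, -50) # gain 2 -> 1
  expect_equal(s$threshold_change_pct, 0.6, tolerance = 1e-8)
  expect_equal(s$baseline_change_pct, 5, tolerance = 1e-8)
})

test_that("dual-condition model is symmetric and separates c from d", {
  sp <- small_stim_pair(800, seed = 31)
  u <- small_unit()
  sim <- simulate_responses(u, sp$low, sp$high, seed = 77, noise_sd = 1)
  rows <- usable_rows(sim$X_low)

  # identical data in both slots: no gain or threshold change
  fit0 <- fit_dual_condition_model(sim$X_low, sim$y_low, sim$X_low,
                                   sim$y_low, rows_low = rows,
                                   rows_high = rows)
  s0 <- summarize_changes(fit0)
  expect_lt(abs(s0$gain_change_pct), 2)
  expect_lt(abs(s0$threshold_change_pct), 2)

  # threshold-only shift: gain stays put, threshold moves by the set amount
  u_thr <- small_unit(gain_change_pct = 0, threshold_change_pct = 25,
                      c_low = 4)
  sim_t <- simulate_responses(u_thr, sp$low, sp$high, seed = 78,
                              noise_sd = 0.5)
  fit_t <- fit_dual_condition_model(sim_t$X_low, sim_t$y_low, sim_t$X_high,
                                    sim_t$y_high, rows_low = rows,
                                    rows_high = rows)
  s_t <- summarize_changes(fit_t)
  expect_lt(abs(s_t$gain_change_pct), 5)
  expect_equal(s_t$threshold_change_pct, 25, tolerance = 5)
})

test_that("shared-parameter objective never beats its own restriction", {
  sp <- small_stim_pair(600, seed = 32)
  u <- small_unit()
  sim <- simulate_responses(u, sp$low, sp$high, seed = 79, noise_sd = 2)
  rows <- usable_rows(sim$X_low)
  fit <- fit_dual_condition_model(sim$X_low, sim$y_low, sim$X_high,
                                  sim$y_high, rows_low = rows,
                                  rows_high = rows)
  # evaluate the joint objective at the naive shared-(a, b) restriction of
  # the per-condition free fits; the optimised joint fit must not be worse
  a_bar <- mean(c(fit$free_low$a, fit$free_high$a))
  b_bar <- mean(c(fit$free_low$b, fit$free_high$b))
  restr <- sum((sim$y_low[rows] -
                  sigmoid_eval(fit$z_low,
                               sigmoid_params(a_bar, b_bar, fit$free_low$c,
                                              fit$free_low$d)))^2) +
    sum((sim$y_high[rows] -
           sigmoid_eval(fit$z_high,
                        sigmoid_params(a_bar, b_bar, fit$free_high$c,
                                       fit$free_high$d)))^2)
  expect_lte(fit$fit_error, restr * (1 + 1e-8))
})

test_that("a simulated halving of gain is recovered at moderate noise", {
  sp <- small_stim_pair(800, seed = 33)
  u <- small_unit() # true gain change -50%
  rows <- usable_rows(build_design_tensor(sp$low$levels, 8))
  gc <- vapply(1:20, function(i) {
    sim <- simulate_responses(u, sp$low, sp$high, seed = 500 + i,
                              noise_sd = 2)
    fit <- fit_dual_condition_model(sim$X_low, sim$y_low, sim$X_high,
                                    sim$y_high, rows_low = rows,
                                    rows_high = rows)
    summarize_changes(fit)$gain_change_pct
  }, numeric(1))
  expect_lt(abs(median(gc) + 50), 5)
})
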