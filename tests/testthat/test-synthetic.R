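test_that("unit generation is deterministic and encodes the gain change", {
  u1 <- generate_unit(seed = 5)
  u2 <- generate_unit(seed = 5)
  expect_identical(u1, u2)

  # -50% gain change means the inverse slope exactly doubles
  expect_equal(u1$sigmoid_high$d, 2 * u1$sigmoid_low$d)
  u3 <- generate_unit(gain_change_pct = -20)
  expect_equal(u3$sigmoid_high$d, u3$sigmoid_low$d / 0.8, tolerance = 1e-12)

  # best frequency snaps to the nearest grid tone
  g <- make_tone_grid(1000, 64000, 0.25)
  u4 <- generate_unit(bf_hz = 9500, grid = g)
  i_bf <- which.max(u4$strf$k_f)
  expect_equal(g$frequencies[i_bf],
               g$frequencies[which.min(abs(log2(g$frequencies / 9500)))])

  # history kernel follows the fitting normalisation
  expect_equal(sum(u1$strf$k_h^2), 1, tolerance = 1e-12)
})

test_that("simulated responses are reproducible and respect nonnegativity", {
  sp <- small_stim_pair(300, seed = 41)
  u <- small_unit(a = 2, noise_sd = 30)
  s1 <- simulate_responses(u, sp$low, sp$high, seed = 9)
  s2 <- simulate_responses(u, sp$low, sp$high, seed = 9)
  expect_identical(s1$y_low, s2$y_low)
  expect_true(all(s1$y_low >= 0) && all(s1$y_high >= 0))
  expect_gt(mean(s1$y_low == 0), 0) # the clip actually binds at this noise
})

test_that("the full pipeline recovers a noiseless unit's gain change", {
  g <- make_tone_grid(1000, 64000, 0.25)
  low <- draw_chord_levels(drc_level_spec(80, 20), 1600, g, seed = 61)
  high <- draw_chord_levels(drc_level_spec(80, 40), 1600, g, seed = 62)
  u <- generate_unit()
  sim <- simulate_responses(u, low, high, seed = 63, noise_sd = 0)
  rows <- usable_rows(sim$X_low)
  fit <- fit_dual_condition_model(sim$X_low, sim$y_low, sim$X_high,
                                  sim$y_high, rows_low = rows,
                                  rows_high = rows)
  expect_equal(summarize_changes(fit)$gain_change_pct, -50, tolerance = 1)
})

test_that("overwhelming noise fails the predictive screen", {
  sp <- small_stim_pair(600, seed = 42)
  u <- small_unit()
  sim <- simulate_responses(u, sp$low, sp$high, seed = 10, noise_sd = 2000)
  cv <- cross_validated_cc(sim$X_low, sim$y_low)
  expect_false(cv$predictive)
})

test_that("noise calibration hits the requested predictive ceiling", {
  sp <- small_stim_pair(800, seed = 43)
  u <- small_unit()
  ns <- calibrate_noise_sd(u, sp$low, target_cc = 0.5)
  X <- build_design_tensor(sp$low$levels, 8)
  z <- predict(u$strf, X)
  f <- sigmoid_eval(z, u$sigmoid_low)
  # attainable correlation between the noiseless signal and noisy response
  cc <- vapply(1:10, function(i) {
    cor(f, f + with_seed_test(50 + i, rnorm(length(f), 0, ns)))
  }, numeric(1))
  expect_equal(mean(cc), 0.5, tolerance = 0.05)
})

test_that("raw-trace simulation is seeded and silent at zero rate", {
  flat <- simulate_raw_trace(rep(0, 20), noise_sd = 0, seed = 1)
  expect_true(all(flat$samples == 0))
  t1 <- simulate_raw_trace(rep(30, 20), noise_sd = 2, seed = 4)
  t2 <- simulate_raw_trace(rep(30, 20), noise_sd = 2, seed = 4)
  expect_identical(t1$samples, t2$samples)
  # doubling the rate roughly doubles the mean MUA envelope
  m1 <- mean(extract_mua(simulate_raw_trace(rep(10, 400), noise_sd = 0,
                                            seed = 6))$samples)
  m2 <- mean(extract_mua(simulate_raw_trace(rep(20, 400), noise_sd = 0,
                                            seed = 6))$samples)
  expect_equal(m2 / m1, 2, tolerance = 0.3)
})

test_that("laminar LFP simulation round-trips and scales with noise", {
  depths <- seq(25, by = 50, length.out = 12)
  fm <- build_forward_matrix(depths)
  C0 <- outer(c(1, 1, 1.5, -1.5, -1, -0.7, -0.4, -0.2, -0.1, 0, 0, 0),
              exp(-((1:30 - 12) / 5)^2))
  est0 <- estimate_csd(simulate_laminar_lfp(C0, fm, noise_sd = 0), fm)
  expect_lt(max(abs(est0$csd - C0)), 1e-10)

  border <- find_reversal_depth(est0, window = 8:16)
  expect_equal(as.numeric(border), (depths[3] + depths[4]) / 2)

  # same seed, doubled noise SD: estimation error scales exactly linearly
  err <- vapply(c(0.5, 1), function(s) {
    est <- estimate_csd(simulate_laminar_lfp(C0, fm, noise_sd = s, seed = 2),
                        fm)
    sqrt(mean((est$csd - C0)^2))
  }, numeric(1))
  expect_equal(err[2], 2 * err[1], tolerance = 1e-10)
})

test_that("population tables mirror the requested laminar composition", {
  spec <- population_spec(seed = 14)
  tab <- simulate_gain_table(spec)
  expect_equal(nrow(tab), 21 + 39 + 50 + 24)
  expect_equal(as.integer(table(tab$layer)), c(21, 39, 50, 24))
  expect_identical(tab, simulate_gain_table(spec))
  # per-layer sample means stay near the configured truth
  m <- tapply(tab$gain_change_pct, tab$layer, mean)
  expect_equal(as.numeric(m), c(-41.6, -54.2, -60.6, -65.1), tolerance = 12)

  units <- generate_population(population_spec(
    n_per_layer = c("2/3" = 2, "4" = 2, "5" = 2, "6" = 2),
    mean_gain_change = c("2/3" = -40, "4" = -50, "5" = -60, "6" = -65),
    seed = 15
  ), grid = small_grid())
  expect_length(units, 8)
  truth <- attr(units, "truth")
  expect_equal(units[[1]]$gain_change_pct, truth$gain_change_pct[1])
  depths <- vapply(units, function(u) u$depth_um, numeric(1))
  expect_equal(as.character(assign_layer(depths)), as.character(truth$layer))
})
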