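#' Generate a synthetic linear-nonlinear unit with known gain control
#'
#' Builds a model neuron of the same class the pipeline fits: a separable
#' STRF (Gaussian frequency bump, exponentially decaying history kernel)
#' followed by per-condition sigmoid nonlinearities. The contrast-dependent
#' gain change is specified directly: `d_high = d_low / (1 + gain_change_pct
#' / 100)`, so -50% means the gain 1/d exactly halves under high contrast.
#' The unit operates on level deviations from its adaptation level (the
#' stimulus mean, stored as the STRF `center`).
#'
#' Default kernel shapes: frequency bump SD 0.5 octave around the best
#' frequency, history decay time constant 40 ms - qualitatively typical of
#' auditory cortex STRFs. The history kernel is normalised to unit Euclidean
#' norm (the fitting convention), so `kf_peak` sets the kernel gain in
#' uV/dB.
#'
#' @param bf_hz Best frequency in Hz (snapped to the nearest grid tone).
#' @param gain_change_pct True gain change in percent (negative = reduction
#'   under high contrast).
#' @param grid Tone grid ([make_tone_grid()]); default 1-64 kHz, 1/4 octave.
#' @param history_steps,step_s History length (lags) and lag duration.
#' @param kf_peak Peak of the frequency kernel before normalisation
#'   (uV/dB); the default 0.6 matches a typical low-contrast kernel peak.
#' @param kf_sd_oct Frequency bump SD in octaves.
#' @param kh_tau_s History decay time constant in seconds.
#' @param a,b Sigmoid baseline and range (uV), shared across conditions.
#'   The default baseline (60 uV) is well above typical response-noise SDs,
#'   reflecting that a chord-binned analog-MUA envelope rides on the
#'   envelope of the recording noise floor plus spontaneous activity, whose
#'   mean exceeds its bin-to-bin SD; the zero-clip of the forward model then
#'   almost never binds.
#' @param c_low Threshold in the low-contrast condition (z units).
#' @param threshold_change_pct True threshold change in percent.
#' @param d_low Inverse slope in the low-contrast condition (z units). The
#'   default (6) is about one low-contrast drive SD for the default kernel,
#'   placing the unit in the threshold-to-rising-phase regime with mild
#'   saturation, as most cortical multiunits show.
#' @param noise_sd Response noise SD in uV (`NULL` to set later, e.g. via
#'   [calibrate_noise_sd()]).
#' @param adaptation_level_db Level the unit is adapted to (the STRF
#'   centring constant).
#' @param depth_um,penetration_id Recording metadata for laminar analyses.
#' @param seed Seed recorded with the unit (generation is deterministic).
#' @return A `synthetic_unit`: list with `strf` (true `separable_strf`),
#'   `sigmoid_low`, `sigmoid_high`, `gain_change_pct`, `noise_sd`, `depth_um`,
#'   `penetration_id`, `seed`.
#' @export
generate_unit <- function(bf_hz = 9500, gain_change_pct = -50,
                          grid = make_tone_grid(1000, 64000, 0.25),
                          history_steps = 16, step_s = 0.025,
                          kf_peak = 0.6, kf_sd_oct = 0.5, kh_tau_s = 0.04,
                          a = 60, b = 15, c_low = 2,
                          threshold_change_pct = 0, d_low = 6,
                          noise_sd = 1, adaptation_level_db = 80,
                          depth_um = NA_real_, penetration_id = NA,
                          seed = 1) {
  stopifnot(gain_change_pct > -100)
  oct <- log2(grid$frequencies / bf_hz)
  i_bf <- which.min(abs(oct))
  kf <- kf_peak * exp(-(log2(grid$frequencies / grid$frequencies[i_bf]))^2 /
                        (2 * kf_sd_oct^2))
  kh <- exp(-((seq_len(history_steps) - 1) * step_s) / kh_tau_s)
  kh <- kh / sqrt(sum(kh^2))
  strf <- list(k0 = 0, k_f = kf, k_h = kh, center = adaptation_level_db,
               step_s = step_s, frequencies = grid$frequencies)
  class(strf) <- "separable_strf"
  d_high <- d_low / (1 + gain_change_pct / 100)
  c_high <- c_low * (1 + threshold_change_pct / 100)
  unit <- list(
    strf = strf,
    sigmoid_low = sigmoid_params(a, b, c_low, d_low),
    sigmoid_high = sigmoid_params(a, b, c_high, d_high),
    gain_change_pct = gain_change_pct,
    threshold_change_pct = threshold_change_pct,
    noise_sd = noise_sd, grid = grid,
    depth_um = depth_um, penetration_id = penetration_id, seed = seed
  )
  class(unit) <- "synthetic_unit"
  unit
}

#' Simulate binned responses of a synthetic unit to a stimulus pair
#'
#' Forward model: linear drive z through the unit's true STRF, per-condition
#' sigmoid, additive Gaussian noise, clipped at zero to respect the
#' nonnegativity of the analog MUA envelope.
#'
#' @param unit A [generate_unit()] unit.
#' @param stim_low,stim_high `drc_stimulus` objects sharing the unit's grid.
#' @param seed Seed for the response noise.
#' @param noise_sd Noise SD (uV); defaults to the unit's.
#' @return List with `y_low`, `y_high` (uV per chord), `z_low`, `z_high`
#'   (the true drives) and the design tensors `X_low`, `X_high`.
#' @export
simulate_responses <- function(unit, stim_low, stim_high, seed = unit$seed,
                               noise_sd = unit$noise_sd) {
  stopifnot(inherits(unit, "synthetic_unit"),
            ncol(stim_low$levels) == length(unit$strf$k_f),
            ncol(stim_high$levels) == length(unit$strf$k_f))
  h <- length(unit$strf$k_h)
  X_low <- build_design_tensor(stim_low$levels, h, unit$strf$step_s)
  X_high <- build_design_tensor(stim_high$levels, h, unit$strf$step_s)
  z_low <- predict(unit$strf, X_low)
  z_high <- predict(unit$strf, X_high)
  f_low <- sigmoid_eval(z_low, unit$sigmoid_low)
  f_high <- sigmoid_eval(z_high, unit$sigmoid_high)
  noise <- with_seed(seed, {
    list(l = stats::rnorm(length(f_low), 0, noise_sd),
         h = stats::rnorm(length(f_high), 0, noise_sd))
  })
  list(
    y_low = pmax(f_low + noise$l, 0),
    y_high = pmax(f_high + noise$h, 0),
    z_low = z_low, z_high = z_high,
    X_low = X_low, X_high = X_high
  )
}

#' Choose a response noise level targeting a given predictive CC
#'
#' Sets the additive noise SD so that the best attainable test correlation
#' of the (noise-free) model prediction is approximately `target_cc`: with
#' signal SD s, noise SD `s * sqrt(1 / cc^2 - 1)` gives correlation cc
#' between the noiseless signal and the noisy response. Computed from the
#' unit's own forward model on the supplied stimulus - a forward
#' calculation, not a fit.
#'
#' @param unit A synthetic unit.
#' @param stim A `drc_stimulus` (typically the low-contrast condition).
#' @param target_cc Target correlation in (0, 1).
#' @return Noise SD in uV.
#' @export
calibrate_noise_sd <- function(unit, stim, target_cc = 0.2) {
  stopifnot(target_cc > 0, target_cc < 1)
  h <- length(unit$strf$k_h)
  X <- build_design_tensor(stim$levels, h, unit$strf$step_s)
  rows <- fit_rows_for(X)
  z <- predict(unit$strf, X)[rows]
  s <- stats::sd(sigmoid_eval(z, unit$sigmoid_low))
  s * sqrt(1 / target_cc^2 - 1)
}

#' Simulate a raw voltage trace with spike wavelets
#'
#' Generates wideband extracellular voltage for testing the MUA extraction
#' chain: spikes are drawn from an inhomogeneous Poisson process driven by
#' `rate_series` (with a 1-ms refractory period so wavelet overlaps stay
#' rare), each spike inserts a 1-ms biphasic wavelet (one cycle of a 1-kHz
#' sine, energy inside the 300-6,000 Hz spike band), and Gaussian noise is
#' added.
#'
#' @param rate_series Firing rate per bin in Hz.
#' @param fs Output sample rate in Hz (>= 24 kHz).
#' @param bin_s Duration of each rate bin in seconds.
#' @param spike_amp_uv Peak wavelet amplitude in uV.
#' @param noise_sd Additive noise SD in uV.
#' @param seed Seed.
#' @return A [raw_trace()] with attribute `spike_times` (s).
#' @export
simulate_raw_trace <- function(rate_series, fs = 24000, bin_s = 0.025,
                               spike_amp_uv = 50, noise_sd = 0, seed = 1) {
  stopifnot(fs >= 24000, all(rate_series >= 0))
  n_samp <- round(length(rate_series) * bin_s * fs)
  rate_per_sample <- rep(rate_series, each = round(bin_s * fs))[seq_len(n_samp)]
  refr <- round(0.001 * fs)
  out <- with_seed(seed, {
    spk <- which(stats::runif(n_samp) < rate_per_sample / fs)
    if (length(spk) > 1) {
      keep <- c(TRUE, diff(spk) > refr)
      # enforce the refractory period sequentially
      last <- spk[1]
      for (i in seq_along(spk)[-1]) {
        if (spk[i] - last > refr) {
          last <- spk[i]
        } else {
          keep[i] <- FALSE
        }
      }
      spk <- spk[keep]
    }
    x <- numeric(n_samp)
    wl_n <- round(0.001 * fs)
    wavelet <- spike_amp_uv * sin(2 * pi * (seq_len(wl_n) - 1) / wl_n)
    for (s in spk) {
      idx <- s:min(s + wl_n - 1L, n_samp)
      x[idx] <- x[idx] + wavelet[seq_along(idx)]
    }
    if (noise_sd > 0) x <- x + stats::rnorm(n_samp, 0, noise_sd)
    list(x = x, spk = spk)
  })
  tr <- raw_trace(out$x, fs)
  attr(tr, "spike_times") <- (out$spk - 1) / fs
  tr
}

#' Simulate laminar LFPs from a known current source density
#'
#' Forward-projects a known CSD through the delta-source electrostatic model
#' (`phi = P %*% C`) and adds Gaussian noise, providing ground truth for the
#' inverse estimate.
#'
#' @param true_csd Matrix (channels x time) of source density.
#' @param fm A [build_forward_matrix()] model with matching channel count.
#' @param noise_sd Additive noise SD (uV).
#' @param seed Seed.
#' @param fs Sample rate passed through to the LFP container.
#' @return A [laminar_lfp()].
#' @export
simulate_laminar_lfp <- function(true_csd, fm, noise_sd = 0, seed = 1,
                                 fs = NULL) {
  true_csd <- as.matrix(true_csd)
  stopifnot(nrow(true_csd) == nrow(fm$P))
  phi <- fm$P %*% true_csd
  if (noise_sd > 0) {
    phi <- phi + with_seed(seed, {
      matrix(stats::rnorm(length(phi), 0, noise_sd), nrow(phi), ncol(phi))
    })
  }
  laminar_lfp(phi, fm$depths_um, fs = fs)
}

#' Specification of a synthetic laminar population
#'
#' Defaults mirror the laminar composition reported for mouse auditory
#' cortex multiunits under contrast-varying DRC stimulation: unit counts
#' (21, 39, 50, 24) and mean gain changes (-41.6, -54.2, -60.6, -65.1)% for
#' layers 2/3, 4, 5 and 6, with a within-layer SD of 15 percentage points,
#' distributed over 17 penetrations. These are simulation defaults for
#' recovery and power studies, not reproduction claims about any recording.
#'
#' @param n_per_layer Named integer vector of unit counts per layer.
#' @param mean_gain_change Named numeric vector of true mean gain changes
#'   (percent) per layer.
#' @param sd_gain_change Within-layer SD of true gain changes (percentage
#'   points).
#' @param penetration_sd SD of additive per-penetration offsets (percentage
#'   points).
#' @param n_penetrations Number of electrode penetrations.
#' @param target_cc Predictive CC the response noise is calibrated to.
#' @param seed Seed.
#' @return A `population_spec` list.
#' @export
population_spec <- function(
    n_per_layer = c("2/3" = 21, "4" = 39, "5" = 50, "6" = 24),
    mean_gain_change = c("2/3" = -41.6, "4" = -54.2, "5" = -60.6,
                         "6" = -65.1),
    sd_gain_change = 15, penetration_sd = 5, n_penetrations = 17,
    target_cc = 0.2, seed = 1) {
  stopifnot(identical(names(n_per_layer), names(mean_gain_change)))
  sp <- list(
    n_per_layer = n_per_layer, mean_gain_change = mean_gain_change,
    sd_gain_change = sd_gain_change, penetration_sd = penetration_sd,
    n_penetrations = n_penetrations, target_cc = target_cc, seed = seed
  )
  class(sp) <- "population_spec"
  sp
}

#' Simulate a population table of true gain changes
#'
#' Draws per-unit true gain changes directly at the table level (layer mean
#' + penetration offset + unit noise), for statistics-stage simulations such
#' as ANOVA power studies that do not need the full encoding-model forward
#' simulation.
#'
#' @param spec A [population_spec()].
#' @param seed Seed (defaults to the spec's).
#' @return Data frame with `unit`, `layer`, `penetration_id`,
#'   `gain_change_pct` and `true_layer_mean`.
#' @export
simulate_gain_table <- function(spec, seed = spec$seed) {
  layers <- names(spec$n_per_layer)
  with_seed(seed, {
    pen_eff <- stats::rnorm(spec$n_penetrations, 0, spec$penetration_sd)
    rows <- lapply(layers, function(ly) {
      n <- spec$n_per_layer[[ly]]
      pen <- sample(seq_len(spec$n_penetrations), n, replace = TRUE)
      data.frame(
        layer = ly, penetration_id = pen,
        gain_change_pct = spec$mean_gain_change[[ly]] + pen_eff[pen] +
          stats::rnorm(n, 0, spec$sd_gain_change),
        true_layer_mean = spec$mean_gain_change[[ly]],
        stringsAsFactors = FALSE
      )
    })
    tab <- do.call(rbind, rows)
    tab$unit <- seq_len(nrow(tab))
    tab$layer <- factor(tab$layer, levels = layers)
    tab$penetration_id <- factor(tab$penetration_id,
                                 levels = seq_len(spec$n_penetrations))
    tab[, c("unit", "layer", "penetration_id", "gain_change_pct",
            "true_layer_mean")]
  })
}

#' Generate a full synthetic population of LN units
#'
#' Draws units layer by layer per the spec: each unit gets a best frequency
#' drawn log-uniformly over the central grid octaves, a depth uniform within
#' its layer's boundaries, a penetration, and a true gain change drawn from
#' its layer's distribution. Response noise is calibrated per unit to the
#' spec's `target_cc` once the stimulus is known (see
#' [calibrate_noise_sd()]).
#'
#' @param spec A [population_spec()].
#' @param grid Tone grid for the units' STRFs.
#' @param seed Seed (defaults to the spec's).
#' @return List of `synthetic_unit` objects; the drawn table is attached as
#'   attribute `truth`.
#' @export
generate_population <- function(spec,
                                grid = make_tone_grid(1000, 64000, 0.25),
                                seed = spec$seed) {
  truth <- simulate_gain_table(spec, seed = seed)
  bounds <- c(0, 225, 425, 675, 900)
  names(bounds) <- NULL
  layer_lo <- c("2/3" = 0, "4" = 225, "5" = 425, "6" = 675)
  layer_hi <- c("2/3" = 225, "4" = 425, "5" = 675, "6" = 900)
  f_rng <- range(grid$frequencies)
  units <- with_seed(child_seed(seed, 2), {
    lapply(seq_len(nrow(truth)), function(i) {
      ly <- as.character(truth$layer[i])
      bf <- 2^stats::runif(1, log2(f_rng[1] * 2), log2(f_rng[2] / 2))
      depth <- stats::runif(1, layer_lo[[ly]], layer_hi[[ly]])
      generate_unit(
        bf_hz = bf, gain_change_pct = truth$gain_change_pct[i],
        grid = grid, depth_um = depth,
        penetration_id = truth$penetration_id[i],
        seed = child_seed(seed, 100 + i)
      )
    })
  })
  attr(units, "truth") <- truth
  units
}
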