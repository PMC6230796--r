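#' Log-spaced tone grid for dynamic random chord stimuli
#'
#' Constructs the carrier-frequency grid of a DRC stimulus: tones log-spaced
#' between `f_min` and `f_max` at a fixed fraction of an octave. The octave
#' span `log2(f_max / f_min)` must be an integer multiple of `spacing` so
#' that both endpoints fall on the grid.
#'
#' @param f_min,f_max Grid endpoints in Hz (`f_min <= f_max`).
#' @param spacing Spacing between neighbouring tones in octaves (> 0 unless
#'   `f_min == f_max`).
#' @return A `tone_grid` object: list with `frequencies` (Hz, increasing) and
#'   `spacing_octaves`.
#' @examples
#' g <- make_tone_grid(1000, 64000, 0.25)
#' length(g$frequencies)  # 25 tones spanning 6 octaves
#' @export
make_tone_grid <- function(f_min, f_max, spacing) {
  stopifnot(is.numeric(f_min), is.numeric(f_max), f_min > 0, f_max >= f_min)
  if (f_max == f_min) {
    g <- list(frequencies = f_min, spacing_octaves = 0)
    class(g) <- "tone_grid"
    return(g)
  }
  stopifnot(is.numeric(spacing), spacing > 0)
  span <- log2(f_max / f_min)
  n_steps <- span / spacing
  if (abs(n_steps - round(n_steps)) > 1e-8) {
    stop(sprintf(
      "octave span %.6g is not an integer multiple of spacing %.6g octaves",
      span, spacing
    ))
  }
  n_steps <- round(n_steps)
  freqs <- f_min * 2^(spacing * (0:n_steps))
  freqs[n_steps + 1] <- f_max  # pin the endpoint exactly
  g <- list(frequencies = freqs, spacing_octaves = spacing)
  class(g) <- "tone_grid"
  g
}

#' @export
print.tone_grid <- function(x, ...) {
  cat(sprintf(
    "<tone_grid> %d tones, %.4g-%.4g Hz, %.3g octave spacing\n",
    length(x$frequencies), min(x$frequencies), max(x$frequencies),
    x$spacing_octaves
  ))
  invisible(x)
}

#' Tone-level distribution for a DRC condition
#'
#' Levels of each tone in each chord are drawn i.i.d. from a continuous
#' uniform distribution centred on `mean_db` with total width `range_db`
#' (support `mean_db +/- range_db / 2`). The width sets the stimulus
#' contrast: widening the support raises both the level SD and the Weber
#' contrast of the corresponding pressure distribution.
#'
#' @param mean_db Mean level in dB SPL.
#' @param range_db Width of the uniform support in dB (>= 0). 20 dB and
#'   40 dB are the conventional low- and high-contrast conditions.
#' @return A `drc_level_spec` object.
#' @export
drc_level_spec <- function(mean_db = 80, range_db = 20) {
  stopifnot(is.numeric(mean_db), is.numeric(range_db), range_db >= 0)
  s <- list(
    mean_db = mean_db, range_db = range_db,
    support = c(mean_db - range_db / 2, mean_db + range_db / 2)
  )
  class(s) <- "drc_level_spec"
  s
}

#' Draw the chord-level matrix of a DRC stimulus
#'
#' Generates the level matrix of a dynamic random chord sequence: one row per
#' 25-ms chord, one column per grid tone, entries i.i.d. uniform over the
#' spec's support. Reproducible from `seed`; the caller's RNG state is left
#' untouched.
#'
#' @param spec A [drc_level_spec()].
#' @param n_chords Number of chords (> 0); 1600 chords of 25 ms give the
#'   standard 40-s sequence.
#' @param grid A [make_tone_grid()] grid.
#' @param seed Integer seed.
#' @param chord_duration,ramp_duration Chord slot and cross-fade ramp
#'   durations in seconds.
#' @param condition_label Optional label, e.g. `"low"` or `"high"`.
#' @return A `drc_stimulus`: list with `levels` (n_chords x n_tones, dB SPL),
#'   `grid`, `spec`, timing fields and `seed`.
#' @export
draw_chord_levels <- function(spec, n_chords, grid, seed,
                              chord_duration = 0.025, ramp_duration = 0.005,
                              condition_label = NULL) {
  stopifnot(inherits(spec, "drc_level_spec"), inherits(grid, "tone_grid"))
  stopifnot(n_chords > 0, chord_duration > 0, ramp_duration >= 0,
            ramp_duration < chord_duration)
  n_tones <- length(grid$frequencies)
  levels <- with_seed(seed, {
    matrix(
      stats::runif(n_chords * n_tones, spec$support[1], spec$support[2]),
      nrow = n_chords, ncol = n_tones
    )
  })
  colnames(levels) <- signif(grid$frequencies, 8)
  stim <- list(
    levels = levels, grid = grid, spec = spec,
    chord_duration = chord_duration, ramp_duration = ramp_duration,
    seed = seed, condition_label = condition_label
  )
  class(stim) <- "drc_stimulus"
  stim
}

#' @export
print.drc_stimulus <- function(x, ...) {
  cat(sprintf(
    "<drc_stimulus> %d chords x %d tones, %.0f ms chords, %s dB SPL%s\n",
    nrow(x$levels), ncol(x$levels), 1000 * x$chord_duration,
    paste(signif(x$spec$support, 4), collapse = "-"),
    if (is.null(x$condition_label)) "" else paste0(" [", x$condition_label, "]")
  ))
  invisible(x)
}

#' Contrast summaries of a DRC stimulus
#'
#' Two operational definitions of stimulus contrast, both computed from the
#' chord-level matrix: `sigma_l`, the SD of all tone levels in dB, and
#' `weber_c`, the Weber contrast sigma_P / mu_P of the corresponding sound
#' pressures p proportional to `10^(L/20)`. Both are 0 for a constant-level
#' stimulus. Summaries are taken over the level matrix, not the rendered
#' waveform, so they are independent of ramp shape and tone phase.
#'
#' @param stim A `drc_stimulus` (or a bare numeric level matrix in dB SPL).
#' @return A list with `sigma_l` (dB) and `weber_c` (dimensionless).
#' @export
compute_contrast <- function(stim) {
  lv <- if (inherits(stim, "drc_stimulus")) stim$levels else stim
  stopifnot(is.numeric(lv), length(lv) > 0)
  lv <- as.numeric(lv)
  sigma_l <- stats::sd(lv)
  if (length(lv) == 1L || sigma_l == 0) {
    return(list(sigma_l = 0, weber_c = 0))
  }
  p <- 10^(lv / 20)
  list(sigma_l = sigma_l, weber_c = stats::sd(p) / mean(p))
}

#' Default level-to-amplitude calibration
#'
#' Maps a tone level in dB SPL to the peak amplitude of a sinusoid whose RMS
#' pressure equals the SPL reference convention: RMS = 20 uPa * 10^(L/20),
#' hence amplitude = sqrt(2) * RMS. Supply your own function to
#' [synthesize_waveform()] to emulate a calibrated playback chain.
#'
#' @param level_db Level(s) in dB SPL.
#' @return Peak amplitude(s) in Pa.
#' @export
spl_to_amplitude <- function(level_db) {
  sqrt(2) * 20e-6 * 10^(level_db / 20)
}

#' Render a DRC stimulus to an audio waveform
#'
#' Each tone of each chord is a sinusoid at its drawn level; consecutive
#' chords are joined by linear amplitude cross-fades: chord n ramps down over
#' the final `ramp_duration` of its slot while chord n + 1 ramps up over the
#' same interval, so total duration stays `n_chords * chord_duration`. Tone
#' phases are drawn once per sequence from the stimulus seed, avoiding
#' coherent onsets.
#'
#' @param stim A `drc_stimulus`.
#' @param fs Sample rate in Hz; must be at least twice the highest grid
#'   frequency (>= 192 kHz recommended for a 64-kHz grid).
#' @param calibration Function mapping dB SPL to peak sinusoid amplitude;
#'   default [spl_to_amplitude()].
#' @return Numeric vector of samples, length `n_chords * chord_duration * fs`
#'   (rounded).
#' @export
synthesize_waveform <- function(stim, fs, calibration = spl_to_amplitude) {
  stopifnot(inherits(stim, "drc_stimulus"), is.numeric(fs), fs > 0)
  n_chords <- nrow(stim$levels)
  n_tones <- ncol(stim$levels)
  total_n <- round(n_chords * stim$chord_duration * fs)
  if (n_tones == 0L) {
    return(numeric(total_n))
  }
  f_max <- max(stim$grid$frequencies)
  if (fs < 2 * f_max) {
    stop(sprintf("fs = %g Hz is below Nyquist for the %g Hz grid", fs, f_max))
  }
  phases <- with_seed(stim$seed + 1L, {
    matrix(stats::runif(n_chords * n_tones, 0, 2 * pi), n_chords, n_tones)
  })
  cd <- stim$chord_duration
  rd <- stim$ramp_duration
  wave <- numeric(total_n)
  amp <- calibration(stim$levels)
  for (ci in seq_len(n_chords)) {
    # chord ci's envelope: rise over [start - rd, start], flat, fall over
    # [end - rd, end]; the rise of chord 1 is clipped at t = 0
    t_start <- (ci - 1) * cd
    t_end <- ci * cd
    i0 <- max(0L, round((t_start - rd) * fs))
    i1 <- min(total_n, round(t_end * fs))
    idx <- (i0 + 1L):i1
    tt <- (idx - 1L) / fs
    env <- rep(1, length(idx))
    rise <- tt < t_start
    env[rise] <- (tt[rise] - (t_start - rd)) / rd
    fall <- tt >= t_end - rd
    env[fall] <- (t_end - tt[fall]) / rd
    env <- pmax(0, pmin(1, env))
    seg <- numeric(length(idx))
    for (fi in seq_len(n_tones)) {
      seg <- seg + amp[ci, fi] *
        sin(2 * pi * stim$grid$frequencies[fi] * tt + phases[ci, fi])
    }
    wave[idx] <- wave[idx] + env * seg
  }
  wave
}

#' Write / read a chord-level matrix as delimited text
#'
#' Tab-delimited, one row per chord, header row giving the tone frequencies
#' in Hz.
#'
#' @param stim A `drc_stimulus`.
#' @param path Output file path.
#' @export
write_levels <- function(stim, path) {
  stopifnot(inherits(stim, "drc_stimulus"))
  utils::write.table(stim$levels, path, sep = "\t", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' @rdname write_levels
#' @return `read_levels()` returns a numeric matrix with frequencies (Hz) as
#'   column names.
#' @export
read_levels <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   check.names = FALSE))
  storage.mode(m) <- "double"
  m
}
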