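#' Raw extracellular voltage trace
#'
#' Thin container for one channel of wideband extracellular voltage.
#'
#' @param samples Voltage samples in microvolts; must be finite.
#' @param fs Sample rate in Hz.
#' @param channel_id Optional channel identifier.
#' @param depth_um Optional contact depth below the pia in micrometres.
#' @return A `raw_trace` object.
#' @export
raw_trace <- function(samples, fs, channel_id = NA, depth_um = NA_real_) {
  stopifnot(is.numeric(samples), all(is.finite(samples)), is.numeric(fs),
            fs > 0)
  tr <- list(samples = as.numeric(samples), fs = fs, channel_id = channel_id,
             depth_um = depth_um)
  class(tr) <- "raw_trace"
  tr
}

#' Analog multiunit activity from a raw trace
#'
#' Computes the analog MUA envelope: band-pass the voltage in the spike band
#' (300-6,000 Hz), full-wave rectify, low-pass below 6,000 Hz, and resample
#' to 12,000 Hz. Band-limited signal energy is a more stable multiunit
#' measure than threshold crossings when spikes are small: it neither
#' undercounts colliding spikes nor overcounts noise-driven crossings. The
#' result is a nonnegative envelope in microvolts.
#'
#' Filters are 4th-order Butterworth applied forward-backward (zero phase),
#' so envelope timing is preserved for subsequent 25-ms binning. The 6-kHz
#' low-pass doubles as the anti-alias filter for the 12-kHz output rate;
#' non-integer decimation factors fall back to linear interpolation of the
#' already band-limited envelope.
#'
#' @param trace A [raw_trace()] with `fs > fs_out`.
#' @param band Spike band edges in Hz.
#' @param rect_lp Post-rectification low-pass corner in Hz.
#' @param fs_out Output sample rate in Hz.
#' @return An `analog_mua` object: nonnegative `samples` (uV) at `fs` =
#'   `fs_out`.
#' @export
extract_mua <- function(trace, band = c(300, 6000), rect_lp = 6000,
                        fs_out = 12000) {
  stopifnot(inherits(trace, "raw_trace"))
  fs <- trace$fs
  if (fs <= fs_out) {
    stop(sprintf("fs = %g Hz: cannot downsample to %g Hz", fs, fs_out))
  }
  stopifnot(band[1] > 0, band[2] > band[1], band[2] < fs / 2,
            rect_lp <= fs / 2)
  bp <- signal::butter(4, band / (fs / 2), type = "pass")
  x <- signal::filtfilt(bp, trace$samples)
  x <- abs(x)
  lp <- signal::butter(4, min(rect_lp / (fs / 2), 0.999), type = "low")
  x <- signal::filtfilt(lp, x)
  x <- resample_to(x, fs, fs_out)
  out <- list(samples = pmax(x, 0), fs = fs_out,
              channel_id = trace$channel_id, depth_um = trace$depth_um)
  class(out) <- "analog_mua"
  out
}

#' Local field potential from a raw trace
#'
#' Low-pass filters the voltage below 300 Hz with a digital 8th-order
#' Chebyshev Type I filter (default 0.5 dB passband ripple), applied
#' forward-backward for zero phase lag, with optional integer-factor
#' decimation of the filtered signal.
#'
#' @param trace A [raw_trace()] with `fs > 600` Hz.
#' @param cutoff Low-pass corner in Hz.
#' @param order Filter order.
#' @param ripple_db Passband ripple in dB.
#' @param decimate Integer decimation factor applied after filtering (1 =
#'   keep the input rate).
#' @return An `lfp_trace` object with `samples` (uV) and `fs`.
#' @export
extract_lfp <- function(trace, cutoff = 300, order = 8, ripple_db = 0.5,
                        decimate = 1L) {
  stopifnot(inherits(trace, "raw_trace"))
  fs <- trace$fs
  if (fs <= 2 * cutoff) {
    stop(sprintf("fs = %g Hz too low for a %g Hz low-pass", fs, cutoff))
  }
  ch <- signal::cheby1(order, ripple_db, cutoff / (fs / 2), type = "low")
  x <- signal::filtfilt(ch, trace$samples)
  decimate <- as.integer(decimate)
  stopifnot(decimate >= 1L)
  if (decimate > 1L) {
    x <- x[seq(1L, length(x), by = decimate)]
    fs <- fs / decimate
  }
  out <- list(samples = x, fs = fs, channel_id = trace$channel_id,
              depth_um = trace$depth_um)
  class(out) <- "lfp_trace"
  out
}

#' Bin an MUA envelope into per-chord responses
#'
#' Averages the analog MUA within each chord's presentation window, yielding
#' the response vector y_t that the encoding models are fitted to. Windows
#' are half-open `[start, end)` aligned to chord onsets; response latency is
#' not compensated here because the STRF's history kernel absorbs it.
#'
#' @param mua An `analog_mua` (or any list with `samples` and `fs`).
#' @param n_chords Number of chords.
#' @param chord_duration Chord duration in seconds.
#' @param onset Time of the first chord onset in seconds from trace start.
#' @return A numeric vector of length `n_chords` (uV), with attribute
#'   `chord_duration`.
#' @export
bin_response <- function(mua, n_chords, chord_duration = 0.025, onset = 0) {
  stopifnot(n_chords > 0, chord_duration > 0, onset >= 0)
  x <- mua$samples
  fs <- mua$fs
  t_end <- onset + n_chords * chord_duration
  # last required sample index: greatest i with (i - 1) / fs < t_end
  need <- ceiling(t_end * fs - 1e-9)
  if (length(x) < need) {
    stop(sprintf("trace too short: %d samples, need %d", length(x), need))
  }
  ts <- (seq_along(x) - 1) / fs
  # guard the floor() against floating-point jitter at window boundaries
  bin <- floor(round((ts - onset) / chord_duration, 9)) + 1
  keep <- bin >= 1 & bin <= n_chords
  y <- as.numeric(tapply(x[keep], bin[keep], mean))
  attr(y, "chord_duration") <- chord_duration
  y
}

# Resample a band-limited signal from fs_in to fs_out. Integer decimation
# uses simple sample picking (the caller has already applied an anti-alias
# filter at or below fs_out / 2); otherwise linear interpolation.
resample_to <- function(x, fs_in, fs_out) {
  if (fs_in == fs_out) {
    return(x)
  }
  r <- fs_in / fs_out
  if (abs(r - round(r)) < 1e-9) {
    x[seq(1L, length(x), by = round(r))]
  } else {
    n_out <- floor((length(x) - 1) / r) + 1
    stats::approx(
      x = (seq_along(x) - 1) / fs_in,
      y = x,
      xout = (seq_len(n_out) - 1) / fs_out
    )$y
  }
}
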