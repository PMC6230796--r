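# Small-scale fixtures used across test files. A reduced tone grid and
# shortened history keep model fits fast while exercising the same code
# paths as the full 25-tone / 16-lag configuration.

small_grid <- function() make_tone_grid(1000, 16000, 0.5) # 9 tones, 4 octaves

small_stim_pair <- function(n_chords = 800, seed = 1) {
  g <- small_grid()
  list(
    low = draw_chord_levels(drc_level_spec(80, 20), n_chords, g,
                            seed = seed, condition_label = "low"),
    high = draw_chord_levels(drc_level_spec(80, 40), n_chords, g,
                             seed = seed + 1, condition_label = "high"),
    grid = g
  )
}

small_unit <- function(bf_hz = 4000, ...) {
  generate_unit(bf_hz = bf_hz, grid = small_grid(), history_steps = 8, ...)
}

# rows with complete history, minus the initial adaptation period
usable_rows <- function(X, exclude = 40) {
  which(attr(X, "complete") & seq_len(dim(X)[1]) > exclude)
}

# seeded draws that leave the session RNG untouched
with_seed_test <- function(seed, code) {
  withr::with_seed(seed, code)
}
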