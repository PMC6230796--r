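# contrastgain

Tools for measuring **contrast gain control (CGC)** in auditory cortex from
laminar multielectrode recordings. When the contrast of ongoing stimulation
doubles, cortical neurons roughly halve the gain of their input-output
function, stabilising the neural representation of spectrotemporal
features. This package implements the complete analysis that quantifies
that effect, for electrophysiologists and computational neuroscientists
working with dynamic random chord (DRC) stimulation:

- **`stimgen`** — DRC stimuli with parametric contrast: 25 tones log-spaced
  1–64 kHz (1/4 octave), 25-ms chords with 5-ms cross-fades, tone levels
  i.i.d. uniform with mean 80 dB SPL and range 20 dB (low contrast) or
  40 dB (high contrast); contrast summaries σ_L and Weber c = σ_P/µ_P.
- **`preprocess`** — analog multiunit activity (band-pass 300–6,000 Hz →
  rectify → low-pass → 12 kHz) and LFPs (8th-order Chebyshev I < 300 Hz),
  all zero-phase, binned per chord.
- **`strf`** — separable (rank-1) spectrotemporal receptive fields fitted by
  alternating least squares on a 400-ms (16-lag) stimulus history, with
  cross-validated predictive screening (CC > 0.04 on a held-out 10%) and
  tuning metrics (best frequency, half-max bandwidth, integration time).
- **`gainmodel`** — the dual-condition model: one STRF for both contrast
  conditions plus a sigmoid output nonlinearity
  `F(z) = a + b / (1 + exp(-(z - c)/d))` whose baseline `a` and range `b`
  are shared while threshold `c` and inverse slope `d` vary by condition;
  gain is `1/d`, and the headline statistic is the percentage gain change
  under high contrast (negative = compensation).
- **`csd`** — δ-source inverse current source density (`C = P⁻¹Φ`,
  disk radius 125 µm, conductivity 0.3 S/m), automated detection of the
  L1–L2/3 polarity reversal, and layer assignment from depth below the
  border (2/3: [0, 225) µm; 4: [225, 425); 5: [425, 675); 6: ≥ 675).
- **`stats`** — paired signed-rank tests, k·SD outlier rules, the two-factor
  laminar ANOVA (layer + penetration) with Tukey-Kramer pairwise layer
  contrasts, and the gain–threshold correlation.
- **`synthetic`** — generators for every input with known ground truth:
  linear–nonlinear units with prescribed gain changes, raw voltage with
  spike wavelets, laminar LFPs from known CSDs, and whole populations with
  laminar gain gradients — so each stage is tested by parameter recovery.
- **`pipeline`** — `run_pipeline(config)` orchestrates everything
  end-to-end from a YAML-serialisable config, deterministically per seed.

## Worked example

Simulate one unit whose gain truly halves under doubled contrast, then
recover that from its responses:

```r
library(contrastgain)

grid      <- make_tone_grid(1000, 64000, 0.25)          # 25 tones, 6 octaves
stim_low  <- draw_chord_levels(drc_level_spec(80, 20), 1600, grid, seed = 1)
stim_high <- draw_chord_levels(drc_level_spec(80, 40), 1600, grid, seed = 2)
unlist(compute_contrast(stim_low))
#>   sigma_l   weber_c
#> 5.7731282 0.6390949
unlist(compute_contrast(stim_high))
#>   sigma_l   weber_c
#> 11.600691  1.163745

unit <- generate_unit(bf_hz = 9500, gain_change_pct = -50, seed = 7)
unit$noise_sd <- calibrate_noise_sd(unit, stim_low, target_cc = 0.3)
sim  <- simulate_responses(unit, stim_low, stim_high, seed = 8)

rows <- which(attr(sim$X_low, "complete") & seq_len(1600) > 40)
cross_validated_cc(sim$X_low, sim$y_low, rows = rows)$cc_test
#> [1] 0.1304  (> 0.04: the unit passes the predictive screen)

fit <- fit_dual_condition_model(sim$X_low, sim$y_low, sim$X_high, sim$y_high,
                                rows_low = rows, rows_high = rows)
fit
#> <dual_condition_fit> gain 1/d: 0.114 -> 0.0624 (-45.2%), threshold c: 5.49 -> 6.95 (+26.7%)

tuning_metrics(fit$strf, grid)
#> BF 9514 Hz, bandwidth 1.07 oct, integration time 22 ms
```

The recovered gain change (−45.2%) sits within the single-unit sampling
spread of the simulated −50% at this noise level; the tuning metrics
recover the unit's 9.5-kHz best frequency. Population medians over many
units (see the acceptance script) pin the estimate down to a few
percentage points.

A full population run, from stimuli to the laminar ANOVA report:

```r
res <- run_pipeline(default_config(seed = 1))
res$stats$median_gain_change_pct
cat(res$report, sep = "\n")
```

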