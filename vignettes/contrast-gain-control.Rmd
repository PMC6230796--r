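---
title: "Quantifying contrast gain control in auditory cortex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying contrast gain control in auditory cortex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contrastgain)
```

## The scientific problem

Sensory neurons face a dynamic-range problem: the variance ("contrast") of
natural stimulation changes constantly, while a neuron's output range is
fixed. Contrast gain control (CGC) is the compensatory solution observed in
auditory cortex: when stimulus contrast rises, the slope (gain) of the
neuron's input-output function falls, keeping the representation of
spectrotemporal features stable. This package implements the full analysis
chain needed to measure CGC in laminar multielectrode recordings from
auditory cortex: stimulus generation, signal extraction, encoding-model
fitting, laminar localisation, and population statistics - plus a
synthetic-data generator so every stage can be validated by parameter
recovery against known ground truth.

## Dynamic random chord stimuli and contrast

A DRC is a dense, rapid sequence of chords. Every 25 ms, each of 25 pure
tones (log-spaced 1-64 kHz, 1/4 octave apart) is assigned an independent
level from a uniform distribution; 5-ms linear cross-fades join successive
chords and a 40-s sequence holds 1,600 chords. The *width* of the level
distribution is the contrast dial: a mean of 80 dB SPL with a 20-dB range
is the low-contrast condition, and widening to 40 dB at the same mean is
the high-contrast condition. Both the level SD (`sigma_l`: 5.77 vs
11.55 dB for continuous uniform draws) and the Weber contrast of the
corresponding pressures (`weber_c = sd(p)/mean(p)`, about 0.64 vs 1.17)
approximately double.

Two conventions worth noting. We use a *continuous* uniform distribution
(no step size is implied by a uniform "range"), and contrast summaries are
computed from the level matrix rather than the rendered waveform, whose
ramp segments would add an estimator-dependent term. Published summary
values computed with other estimators (e.g. a level SD near 6.2 dB for a
20-dB range) differ by a few percent from the continuous-uniform values;
the package reports the values implied by its own generator and does not
try to match any particular alternative estimator.

## From raw voltage to responses

Spiking activity is quantified as *analog multiunit activity* (MUA), not
threshold crossings: the voltage is band-passed at 300-6,000 Hz (4th-order
Butterworth), full-wave rectified, low-passed below 6,000 Hz and resampled
to 12 kHz. Band-limited signal energy neither under-counts colliding
spikes nor over-counts noise-driven threshold crossings, which matters
when spikes are small relative to noise. All filters are applied
forward-backward (zero phase) so that envelope timing survives the
subsequent 25-ms binning; responses `y_t` are window means over each
chord, aligned to chord onsets with no latency correction (the encoding
model's history dimension absorbs response latency). LFPs are extracted
with an 8th-order Chebyshev Type I low-pass below 300 Hz (0.5 dB passband
ripple), also zero-phase.

## The encoding model

The model is linear-nonlinear. The linear stage is a spectrotemporal
receptive field (STRF) over the stimulus tensor `X[t, f, h]` - the level
of tone `f` at `h` chords before time `t`, with 16 lags spanning 400 ms:

    z_t = k0 + sum_{f,h} X[t,f,h] * k_f[f] * k_h[h]

The kernel is constrained to be *separable* (rank 1), which cuts the free
parameters from 400 to 41 and in practice predicts held-out responses as
well as or better than full-rank kernels. Fitting is alternating least
squares: each kernel is refit by linear regression with the other fixed,
repeated until the relative change in the sum-of-squares error drops below
1e-6 (at most 100 alternations; the error is non-increasing by
construction). The scale ambiguity of the outer product is fixed by giving
`k_h` unit Euclidean norm with a positive dominant element, so `k_f`
carries the units (uV per dB). Stimulus levels are mean-centred per
condition before fitting; the centre is stored with the kernel and
reapplied at prediction. The first second of stimulation (40 chords) is
excluded from all fitting and evaluation, which also guarantees complete
history for every fitted row.

The output stage is a monotone sigmoid with baseline `a`, range `b`,
threshold `c` and inverse slope `d`:

    F(z) = a + b / (1 + exp(-(z - c) / d))

The neuron's gain is `1/d`. Sigmoids are fitted by bounded quasi-Newton
descent (L-BFGS-B) on the sum-of-squares error from a deterministic set of
starts, one of which is anchored to the ordinary least-squares line
through `(z, y)` - the right starting point when the data only resolve the
near-linear part of the curve. `d` is bounded below by `sd(z)/100`: a
transition narrower than 1% of the drive spread cannot be resolved and
indicates a degenerate step-function fit.

## The dual-condition gain model

CGC is quantified with one STRF fitted jointly to both contrast
conditions, followed by sigmoids that share `a` and `b` across conditions
while `c` and `d` are condition-specific. (Per-condition baseline changes
are small - of order 1% - which justifies sharing `a`; baseline changes
are reported from per-condition fully free fits instead.) The headline
statistic is the gain change `100 * ((1/d_high) - (1/d_low)) / (1/d_low)`;
negative values mean gain reduction under high contrast, and -50% would
exactly compensate a doubling of contrast.

One estimator detail is essential at realistic noise levels. If the drive
`z_t` fed to the sigmoid stage is the in-sample prediction of an STRF
fitted to the same responses, the kernel absorbs response noise, and that
shared noise component dilutes the between-condition slope asymmetry -
gain changes shrink toward zero (classical regression dilution; at a
predictive correlation of 0.2 the bias exceeds 20 percentage points). The
package therefore *cross-fits* the drive: the pooled chords are split into
two interleaved folds, a pooled STRF is fitted to each fold's complement,
and each chord's drive is the projection of its stimulus onto the held-out
*unit-norm kernel direction*. Because DRC levels are white, projecting
both conditions onto the same fixed direction leaves the
between-condition slope ratio - hence the gain ratio - unbiased by kernel
estimation error; noiseless data are unaffected (the held-out direction is
then exact). The reported STRF itself is still fitted on all pooled
chords.

Two caveats follow from the same analysis. First, threshold (`c`)
estimates require resolved curvature: when only the near-linear part of
the sigmoid is identified, `c` and `d` are confounded and per-unit
threshold changes inherit the gain ratio; they are interpretable at
moderate noise but not at the predictive-screen floor. Second, per-unit
gain-change estimates at a test correlation of 0.2 carry a standard
deviation near 16 percentage points - population medians, not single
units, are the meaningful quantity there.

## Unit selection

A unit enters the population analysis only if an STRF fitted to the first
90% of a condition's usable chords predicts the final 10% with a Pearson
correlation above 0.04, in both conditions. The threshold is kept as a
configurable constant; `null_cc_threshold()` re-derives a chance level for
any particular geometry by circularly shifting responses. Note that the
null CC is approximately normal with SD `1/sqrt(n_test)` (about 0.08 for a
160-chord test set), so a 0.04 cut admits a non-trivial fraction of
chance-level units in a single condition; requiring both conditions to
pass sharpens the screen.

## Laminar assignment by inverse CSD

Cortical depth is anchored at the polarity reversal of the
stimulus-evoked current source density at the layer 1 - layer 2/3 border.
CSD is estimated with the delta-source inverse method: current is assumed
to arise in thin disks (diameter 250 um) at each contact plane of a
50-um-spaced laminar probe in a homogeneous medium of conductivity
0.3 S/m. The forward matrix

    P[j,i] = h / (2 sigma) * (sqrt((z_j - z_i)^2 + R^2) - |z_j - z_i|)

maps planar source densities to potentials, and `C = solve(P, phi)`
inverts it. The estimate is linear in the potentials, and conductivity
only rescales it uniformly, leaving the spatial pattern - all that layer
assignment uses - untouched; absolute CSD units are therefore not
validated, the round-trip identity `solve(P, P %*% C) = C` is. Reversal
detection is automated: the most superficial adjacent channel pair whose
early-window (default 5-30 ms) mean CSD changes sign with both magnitudes
above a noise floor (twice the pre-stimulus SD when a baseline is given).
Depths below the border map to layers through half-open intervals:
[0, 225) um layer 2/3, [225, 425) layer 4, [425, 675) layer 5, and 675 um
or deeper layer 6; negative depths are layer 1 and excluded.

## Population statistics

Paired per-unit parameter changes are tested with two-sided Wilcoxon
signed-rank tests (exact null for 25 or fewer non-zero pairs, normal
approximation with continuity correction otherwise). Outliers are flagged
at 1.96 SD from the mean for tuning-parameter comparisons (flagged but
retained in the tests) and excluded at 3 SD for the laminar ANOVA and the
gain-threshold correlation - exactly where exclusion is scientifically
warranted by unstable fits. The laminar analysis is an additive two-factor
fixed-effects ANOVA (gain change ~ layer + penetration, no interaction)
with Tukey-Kramer-corrected pairwise layer contrasts on model-adjusted
means (via `emmeans`). Because the design is unbalanced, the
sum-of-squares type matters: the default is Type III with sum-to-zero
contrasts, matching the default of the commercial statistics toolchain
most electrophysiology labs use, and Types I and II are available through
the `ss_type` argument.

## The synthetic-data generator

`generate_unit()` builds model neurons of exactly the class the pipeline
fits: a Gaussian frequency bump (SD 0.5 octave) around a chosen best
frequency, an exponentially decaying history kernel (time constant 40 ms),
and per-condition sigmoids whose inverse slopes encode a chosen true gain
change (`d_high = d_low / (1 + change/100)`, so -50% doubles `d`).
Defaults place units in the physiological regime: a kernel peak of
0.6 uV/dB; a low-contrast threshold (`c = 2`) slightly above the mean
drive and an inverse slope (`d = 6`) of about one low-contrast drive SD,
giving threshold-plus-rising-phase responses with mild saturation, as most
cortical multiunits show; and a baseline of 60 uV, reflecting that a
chord-binned analog-MUA envelope rides on the envelope of the recording
noise floor plus spontaneous activity, whose mean exceeds its bin-to-bin
SD - so the nonnegativity clip of the forward model rarely binds.
Response noise is additive Gaussian on the binned envelope (matching the
sum-of-squares objective); `calibrate_noise_sd()` sets it so the
*attainable* predictive correlation equals a target (default 0.2, the
bottom of the screened population), via `noise = signal_sd *
sqrt(1/cc^2 - 1)` - a forward calculation, never a fit.

Population simulations default to the reported laminar composition of the
screened mouse auditory cortex sample: 21, 39, 50 and 24 units in layers
2/3, 4, 5 and 6 with mean gain changes -41.6, -54.2, -60.6 and -65.1%, a
within-layer SD of 15 points, and 17 penetrations contributing additive
offsets (SD 5 points). These are simulation settings for recovery and
power studies, not reproduction claims: no recordings are distributed, and
nothing in the test suite asserts agreement with any real-data value.

What the generator deliberately does *not* emulate: slow gain adaptation
after contrast switches (only the steady state is modelled, which is why
the first second is excluded), correlated or signal-dependent noise,
spike-sorting artefacts, across-unit kernel diversity beyond BF and gain,
and any biophysical circuit mechanism. Passing recovery tests therefore
demonstrates estimator correctness under the model's own assumptions, not
robustness to every feature of real recordings.

## Problem sizes and numerical choices

The test suite exercises full-size configurations (1,600 chords, 25
tones, 16 lags) where the scientific claim depends on them - the
gain-recovery and power studies - and reduced ones (9 tones, 8 lags,
600-800 chords) for structural and invariance checks; the acceptance
script runs the 20-unit gain-recovery study at full stimulus size and a
22-unit scaled population through the complete pipeline. Degenerate
inputs are handled explicitly: constant responses give a boundary-flagged
sigmoid and a bias-only STRF; zero-variance held-out responses mark a
unit non-predictive rather than erroring; all-positive CSD profiles raise
"no reversal found". Ties in the layer map fall to the deeper layer
(half-open intervals); the reversal search prefers the most superficial
qualifying pair.

## Known limitations

Separable STRFs cannot represent frequency sweeps (features covarying in
frequency and time); regularised or full-rank estimators are out of
scope. The CSD forward model assumes a homogeneous isotropic medium and
uniform contact spacing. Threshold-change estimates degrade into the gain
ratio when curvature is unresolved (see above). File interchange uses
delimited text and CSV/YAML/JSON only.
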