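---
title: "Models and methods behind myocoh"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind myocoh}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myocoh)
```

`myocoh` implements the analysis chain of an EMG-driven neurofeedback
training protocol for wrist muscle control: EMG conditioning, the
extensor-ratio biofeedback engine, the static-hold tracking-error
assessment, and corticomuscular coherence (CMC) statistics. This vignette
explains the models, the tunable parameters, the numerical choices taken
where the procedure left latitude, and what the synthetic validation does
and does not demonstrate.

## Signal conditioning

EMG is band-pass filtered 15–450 Hz and EEG 5–100 Hz with Butterworth
filters applied forward–backward (`bandpassFilter`, `zeroPhase = TRUE`).
"Order" throughout is the overall filter order; the band-pass design uses
a low-pass prototype of half that order, and the forward–backward pass
doubles the attenuation in dB while cancelling the phase. A "6th-order
zero-phase" EEG filter is thus a 6th-order design applied twice — the
common reading in EEG pipelines, stated explicitly because the phrase is
ambiguous. EEG is then re-referenced to the common average of the
channels retained after bad-channel exclusion (`preprocessEEG`).

Two amplitude envelopes are used:

* `movingEnvelope` — the mean of the rectified signal over a *trailing*
  window, sampled at the output rate. The training feedback ran in real
  time, so a centred window is impossible; the static-hold cursor uses
  the same causal convention (1 s window) for consistency, and the
  training ER uses a 480 ms window at 250 Hz. Output ticks earlier than
  one full window average the samples available so far rather than
  padding with fabricated data; this start-up transient is confined to
  the first window length.
* `hilbertEnvelope` — the magnitude of the FFT-constructed analytic
  signal, used in the CMC pipeline, where the envelope is subsequently
  standardized to zero mean and unit variance per epoch.

Amplitudes feeding the feedback engine are normalized per channel to the
maximal power-grip activity (`normalizationReference`,
`kind = "power_grip_max"`); session-level summaries can instead be
Z-scored against a reference session (`kind = "session_zscore"`).

## The biofeedback engine

The extensor ratio is `ER = E/(E + F)` with `E` and `F` the summed
normalized extensor (ECR + ECU) and flexor (FCR + FCU) envelopes. `ER` is
undefined whenever `E + F` falls below an activity floor (default 0.01,
i.e. 1% of a single channel's grip maximum) — this avoids a 0/0 ratio at
rest, and an undefined `ER` never satisfies the success criteria.

A feedback sample "meets criteria" when the summed extensor activity
exceeds 30% of its summed grip maximum *and* `ER` exceeds the staircase
threshold. A trial succeeds when the criteria hold over a contiguous run
of at least 2 s. "Maintain for 2 s" is read as contiguous; a cumulative
reading is available (`contiguous = FALSE`) but off by default.

The staircase starts at 0.5 each session and moves in 0.3 steps, clipped
to [0.3, 0.97], when the last three outcomes recorded since the previous
adjustment are all successes or all failures; the history is cleared
after any adjustment. Whether the original controller used a strict
block-of-three or a sliding window is not documented; this implementation
checks the last three outcomes *since the last adjustment*, which can
trigger on, e.g., failure–success–success–success, but can never trigger
twice one trial apart. All of these constants are arguments of
`runSession` with the protocol values as defaults.

## Static-hold assessment

The target is a trapezoid spanning 6 s — ramps split symmetrically
1 s + 4 s plateau + 1 s, the split being a package choice since only the
span and plateau are fixed — with the plateau at 15% of the grip maximum,
within a 10 s cursor sweep. The tracking error of a hold is the median of
|cursor − plateau level| over the last 3 s of the plateau: the deviation
is taken about the *target*, not about the sample median, because the
target is the stated reference. Restricting to the last 3 s keeps the
cursor's 1 s trailing window entirely inside the plateau, so no ramp
samples contaminate the error.

Pre/post comparisons pair hold *k* before training with hold *k* after
training (the only pairing available) in a two-sided paired t-test;
zero-variance differences are reported with an explicit `degenerate` flag
rather than an infinite statistic. Group-level comparisons apply the same
test to participant means. No multiple-testing correction is applied at
the group level; reported p-values are raw.

## Coherence statistics

`pooledCoherence` averages Hann-windowed auto- and cross-periodograms
over 512 ms segments at 75% overlap (the defaults), giving a 1.95 Hz
frequency grid. Segments are tiled strictly within epochs: concatenating
unrelated epochs and letting segments straddle the seam would
manufacture spurious spectra. Pooling over channel pairs or participants
extends the epoch lists.

The effective number of independent segments `L` is the
variance-equivalent count: the raw segment count divided by the variance
inflation `1 + 2·Σ_m (1 − m/K)·c_m²`, where `c_m` is the normalized
window overlap correlation at lag `m` shifts (≈ 0.659, 0.167, 0.007 for
Hann at 75% overlap). With epochs, per-epoch counts and inflations
combine as `L = K²/Σ_e K_e·infl_e`. `L` is reported in every spectrum so
an alternative correction can be substituted downstream. The confidence
level `CL = 1 − 0.05^(1/(L−1))` then bounds the null distribution of
estimated coherence: about 95% of bins of two independent signals fall
below it, which the test suite verifies on 120 s records.

Pre/post change uses `FZ = atanh(√Coh)`, whose sampling variance is
approximately `1/(2L)` when the underlying coherence is away from zero.
The per-frequency statistic is
`Z = (FZ_post − FZ_pre)/√(1/(2L_pre) + 1/(2L_post))`, which reduces
exactly to the single-`L` form `√(1/L)` when both spectra share one `L`;
a literal single-`L` mode (`method = "literal"`, `L = min`) is also
provided. Two calibration caveats are deliberate:

* At *zero* underlying coherence the Fisher variance overstates the
  spread of `FZ` (the magnitude estimate is Rayleigh-like), so the Z
  statistic is conservative there. Calibration checks therefore use
  records with nonzero shared coherence under a no-change null, where
  the per-bin SD is ≈ 1.
* Hann tapering correlates *adjacent frequency bins* through spectral
  leakage, which a Stouffer composite `Σz/√n` over a band inherits: under
  a no-change null with nonzero coherence the composite is
  anticonservative. The calibration tests therefore use rectangular,
  non-overlapping segments (`window = "rect"`, `overlap = 0`), where bins
  are independent; even then the empirical rejection rate sits slightly
  above 5% (≈ 6–8%) because bins at the edges of the synthetic drive band
  have inflated variance. The default analysis pipeline keeps the Hann
  window; band composites from overlapped Hann spectra should be read as
  descriptive summaries rather than exact 5%-level tests.

Band composites are computed over alpha (8–12), beta (12–30) and gamma
(30–50 Hz); the 1.95 Hz grid places no bin on a band boundary.

## The synthetic generator

All validation rests on `generateCoherentPair`,
`generateTrainingSession` and `generateStaticHold`, which share a seeded
configuration (`synthConfig`).

**Coherent pairs.** A band-limited drive `s(t)` (white noise restricted
to the 12–30 Hz beta band by an FFT mask) is shared between the EEG
channel, `√r₁·s + n₁` with broadband white `n₁`, and the EMG envelope
modulator, `level·(1 + 0.2·(√r₂·s + m)/sd)` with band-limited independent
`m`. Because drive and noise have flat in-band spectra, the
magnitude-squared coherence between EEG and EMG envelope is exactly
`r₁r₂/((1+r₁)(1+r₂))` in band and zero outside — 0.25 at `r₁ = r₂ = 1`,
0.64 at 4 and 4. The EMG channel is the modulator times a
constant-modulus carrier: a cosine whose instantaneous frequency wanders
randomly around 200 ± 40 Hz. A noise carrier's own Rayleigh envelope
fluctuations would leak into the beta band and make the closed form
unattainable through Hilbert demodulation; the random-FM carrier has a
noise-like broadband spectrum inside the 15–450 Hz EMG band but exactly
unit envelope, so the Hilbert envelope returns the modulator and the
closed form holds for the *full* conditioning path. The modulation depth
(0.2) keeps the modulator positive at 5 SD.

**Training sessions** follow the 7 s rest / 5 s attempt schedule, six
blocks of twenty trials by default. Per-trial activation is log-normal
around `activationLevel` for extensors and `coactivationRatio` times
that for flexors — log-normal keeps amplitudes positive — with
trial-to-trial spread `0.4·(1 − agentSkill)`, so a skill-1 agent is
perfectly reproducible. Attempts are gated with 0.2 s raised-cosine
edges, and a small (0.02) band-limited within-attempt jitter is added.
The resting baseline (default 0.02 of maximum) bounds the best
achievable ER; lowering it (e.g. `baselineLevel = 0.004`) lets a perfect
agent exceed the 0.97 threshold ceiling, which the staircase tests use.

**Static holds** place 16 trapezoids, each preceded by 4 s of rest.
`trackingNoise` is defined at the *cursor* level: slow band-limited
noise (0.05–0.45 Hz, the timescale of human tracking corrections) is
rescaled per record so that its 1 s-smoothed version has exactly the
requested SD. Because this noise decorrelates slowly relative to the 3 s
analysis window, the mean per-hold MAD lands between the population
median of |N(0, σ)| (0.674σ) and the half-normal mean (0.798σ) — about
0.72σ in practice — rather than exactly 0.674σ, which the tests check
against a brute-force simulation of the same noise class.

The generator's defaults are the protocol's task constants where those
exist (trial schedule, 6 × 20 trials, 15% target, 16 holds, staircase
constants, feedback rates and windows). Activation level 0.5,
co-activation 0.3, agent skill 0.7 and the drive power ratios have no
counterpart in the protocol description; they were fixed once at values
that give a mid-range task difficulty and clearly measurable coherence,
and the closed-form examples (0.25, 0.64) exercise the estimator at
moderate and high coupling.

What the generator does *not* emulate: motor-unit dynamics, line noise
or motion artifacts, non-stationary fatigue drifts, volume conduction
between channels, and realistic (much lower) clinical CMC magnitudes.
Passing tests demonstrate that the estimators and statistics are correct
on signals satisfying their assumptions — not that the pipeline is
robust to artifacts of real recordings.

## Degenerate inputs and numerical conventions

* `computeER` returns `NA` below the activity floor; negative inputs are
  rejected.
* `standardizeSeries` and the session Z-score reference reject
  zero-variance input.
* `pairedT` flags exactly- or numerically-constant differences as
  `degenerate` (identical vectors report t = 0, p = 1).
* `spearmanTrend` uses midranks, exact p-values for n ≤ 9 without ties,
  and reports an `all_tied` flag for constant input.
* Coherence values are clamped to [0, 1] against floating-point
  overshoot; `fisherZ` caps its argument below 1 to keep `atanh` finite.
* Butterworth corner frequencies are validated against (0, Nyquist);
  filter responses are checked in the tests against the analog closed
  form at bilinear pre-warped frequencies.

## Problem sizes used by the test suite

The suite favours fixtures large enough for stable statistics yet quick
to simulate: 120 s records for confidence-level coverage (10–20
replicates), 300 s records for closed-form coherence recovery, 150
pre/post pairs of 40 s for Z calibration, 1000-case brute-force oracle
sweeps for the elementary operations, and three seeds for the end-to-end
recovery/no-change scenario, judged by majority. The full demo
(`runDemo`) with seven 120-trial training sessions runs in a few minutes
on one core.
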