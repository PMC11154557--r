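---
title: "Methods: multimodal eating-event detection with bitewatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal eating-event detection with bitewatch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bitewatch)
```

## The problem and the model

Eating is a sequence of phases — ingestion by a hand-to-mouth gesture, food
processing by chewing, deglutition by swallowing — and each phase has a
sensor that sees it best: a wrist inertial unit for gestures, a jaw-mounted
piezoelectric film for chewing, and respiratory inductance plethysmography
(RIP) for swallowing, which briefly interrupts the breathing waveform.
`bitewatch` implements per-measure binary detection ("is this window an
eating gesture / chewing / a swallow?") and quantifies how much adding the
other sensors' features helps each measure.

The three streams run at very different rates (nominally 83, 204 and
6.2 Hz) and their natural analysis units differ: 1 s windows for gestures,
3 s windows for chewing, and variable-length breathing cycles for
swallowing. Rather than resampling to a common clock, the pipeline computes
a fixed number of features per window and aligns windows *across* sensors
by nearest midpoint. This makes the feature count per unit time independent
of sampling rate and keeps each modality's windowing in its own natural
units.

## Synthetic sessions: what they emulate and what they do not

No public dataset exists for this sensor triplet, so the package ships a
session generator that renders a scripted table-top protocol: a 20 s
breath-to-extremes calibration, a ~5 min spoon-fed course, 1 min of random
arm movement, 2 min sitting still with a head scratch every 10 s, 3 min
reading aloud, another still block, a ~3 min hand-fed course, and a final
random-arm minute. Eating courses contain gesture → chew-burst → swallow
cycles roughly every 20 s; still blocks contain isolated saliva swallows.
Course durations marked "~" are drawn within ±10 % of nominal, so sessions
land near 17 minutes.

Waveform families are deliberate idealizations, parameterized in
`generator_config()`:

* **IMU** — gravity (9.81 m/s²) on the resting axis plus white noise;
  spoon gestures add a raised-cosine *plateau* rotation pulse on the
  underarm gyroscope axis (controlled movement, ~3 s), hand gestures a
  sharper *biphasic* pulse (~2 s), both with correlated accelerometer
  excursions; scratching and random-arm blocks add pulses with different
  axis mixtures so the confounders genuinely resemble gestures.
* **Piezo** — slow drift plus noise; chew bursts are amplitude-modulated
  oscillations at the chewing fundamental (default 1.6 Hz, ±2 % per burst)
  with 2nd/3rd harmonics; reading aloud adds lower-amplitude wideband
  activity with a 4 Hz syllabic envelope.
* **RIP** — abdomen and ribs carry phase-locked fractions (0.6 / 0.4) of a
  common volume trace built cycle by cycle: quiet periods drawn around the
  3.6 s mean with 0.25 s jitter, per-cycle amplitude variation, slow drift.
  Each swallow flattens the volume for 0.6 s — long enough to leave ≥ 3
  samples at 6.2 Hz — inside the interior (phase 0.25–0.70) of exactly one
  cycle. Calibration cycles are slow (≈5 s), deep (amplitude ×1.8), and
  start from a forced-exhale trough below the quiet end-exhale level, so
  quiet breathing sits strictly inside the calibration extremes after
  volume scaling.

Ground truth is exact by construction; annotations record every rendered
micro-event. The same `(script, config, seed)` triple is bit-identical.

What the generator does **not** emulate: inter-subject anthropometry,
motion artifacts coupling between sensors, sensor detachment, chewing-rate
variation within a burst, irregular breathing beyond period jitter, or any
physiologically validated waveform shape. Passing the end-to-end tests
therefore demonstrates that the pipeline machinery recovers structure it is
designed for — not that these scores transfer to human data. The held-out
micro-F1 values near 1.0 on clean synthetic sessions should be read as a
correctness ceiling, not a performance claim; real six-subject recordings
of this kind yield scores around 0.6–0.95 depending on the measure.

## Signal formats and filtering choices

All filters are order-4 Butterworth designs applied forward-backward, so
they are zero-phase: a symmetric pulse stays symmetric and window labels
never shift in time. Inputs are extended by odd reflection about their
endpoints before filtering (and trimmed after); without that padding,
forward-backward filtering of drifting records produces large end
transients. Each channel is de-meaned before the high-pass, which makes
"constant in → exactly zero out" hold to machine precision.

Cutoffs are configuration, not dogma (`preprocessing` defaults): IMU
high-pass 0.3 Hz (removes gravity and drift but keeps gesture dynamics,
which live well above 0.5 Hz); piezo high-pass 0.1 Hz; piezo bands
0.5–5 Hz and 5–30 Hz — chewing fundamentals sit at 1–2.5 Hz, so the low
band carries the chewing signature and the band-energy ratio separates
chewing from wideband speech; RIP high-pass 0.05 Hz, deliberately just
above zero so that ~0.28 Hz breathing passes untouched while belt drift is
removed. Aggressive RIP high-passing would deform cycle shapes and shift
detected minima, so both the cutoff and the minima-detection parameters are
exposed rather than fixed.

Piezo variants are standardized per channel ((x − mean)/SD; zero-SD
channels map to zero) to absorb sensor-positioning and gain differences.
Standardization statistics default to the whole record but accept an
explicit fitting span; inside classification, scaling is always re-fitted
on the training split only.

Lung volume is estimated as abdomen + ribs, and mapped affinely so the
calibration interval's minimum is 0 and maximum is 1 — making downstream
features invariant to belt gain, which is arbitrary hardware units.

## Windows, cycles, and normalization

Fixed windows tile from t = 0; a trailing partial window is discarded so
every window carries a full-duration feature contract. Breathing cycles
are split at inhalation minima found by a prominence-based detector
(defaults: prominence 0.1 scaled units, separation ≥ 1.5 s, cycle length
≥ 1.5 s). At 6.2 Hz a plain local-minimum scan would fire on noise;
topographic prominence is the standard remedy and its threshold is the one
truly data-dependent parameter in segmentation.

Each cycle is normalized for shape comparison: time mapped affinely to
[0, 1]; the straight line through the two endpoint values subtracted (so
both endpoints are exactly 0 — the endpoints generally differ, and a
linear baseline is the minimal transform that zeroes both without bending
the interior); then divided by the maximum (peak exactly 1). The transform
is idempotent, and degenerate (constant) cycles are rejected rather than
normalized into NaN.

## Feature registries

Registry sizes are contractual — 27 IMU (10 gyroscope + 17 accelerometer),
29 piezo, 36 RIP (26 raw-shape + 10 normalized-shape) — and carried in
output metadata as `bitewatch-registry-1`.
The individual features are standard statistical and spectral descriptors
of the lineage work each modality builds on: window statistics, magnitudes,
zero crossings and axis correlations for the IMU; per-variant statistics
plus dominant frequency, band powers and spectral entropy for the piezo;
duration/amplitude/slope/derivative/shape statistics plus
neighbouring-cycle ratios for RIP. Degenerate-input rules are explicit:
correlation of a constant axis is 0, spectral entropy of silence is 0, and
a cycle missing a neighbour reports ratio 1 (the "no change" value, chosen
over NA to keep vectors finite). No feature may be NaN or Inf on any input.

## Fusion geometry

An anchor window (the measure's own modality) links one window per other
included sensor: the candidate with the nearest midpoint, ties broken
toward the earlier window. Past/future context is appended per side; the
per-side count is `round(context_s / nominal_duration)` with half rounded
away from zero and nominal durations 1 s, 3 s, and 3.6 s (the mean
breathing-cycle duration standing in for RIP's variable windows). The
rounding rule is the one choice that reproduces the documented 3 s–3 s
layout — 3 IMU windows, 1 piezo window, and 1 RIP cycle per side (3/3.6
rounds to 1, where flooring would give 0), i.e. 13 windows and
7·27 + 3·29 + 3·36 = 384 features; for unanchored cases (7 s, 10 s, 13 s)
the same rule is applied uniformly and recorded in output metadata. RIP
context is taken by cycle adjacency (previous/next cycles), not by seconds.
Anchors whose full context would run off either end of the recording are
dropped rather than zero-padded — fabricating silent context would dilute
boundary labels — so vector counts shrink slightly as context grows, and
all vectors under one configuration share one length (the training
contract).

## Classification protocol

Per measure, vectors are labelled 1 iff the anchor's half-open extent
[t_start, t_end) overlaps any annotated interval of that measure by more
than zero seconds; context windows never affect the label. The split is
2:1 train/test, stratified by label, *before* any statistic is fitted;
feature scaling and PCA (smallest component count reaching 95 % retained
variance) are fitted on the training block only. A leave-subjects-out
split (`model_config(split = "by_subject")`) is available for
generalisation studies. The SVM uses an RBF kernel; hyperparameters come
from a randomized search (default 50 draws; C log-uniform on 10⁻²…10³,
kernel width log-uniform on 10⁻⁴…10¹ — wide enough to span under- to
over-fitting on PCA-projected inputs) scored by mean micro-F1 over
stratified 3-fold cross-validation, ties to the earlier draw, refit on the
full training block.

Micro-averaged F1 pools true/false positive/negative counts over classes;
for single-label binary problems it equals accuracy, and the
implementation computes it from pooled counts and reports the trivial
majority-class baseline alongside, since prevalences here are asymmetric
(roughly 8 % gestures, 40 % chewing, 9 % swallows per anchor unit on
default synthetic sessions). Each grid cell (measure × sensor combination
× context configuration; 3 × 4 × 11 = 132 cells in full) carries its own
search, seed, confusion counts and chosen hyperparameters.

## Problem sizes and numerical choices

The shipped analysis and tests run three ~17 min sessions (≈85 k IMU,
≈210 k piezo, ≈6.3 k RIP samples each; ~1020 IMU windows, ~340 piezo
windows, ~280 cycles), with 10 random-search draws per cell and reduced
grids (own-sensor and all-sensor combinations at up to three context
sizes) — sizes chosen so a full run completes in minutes on one core while
every stage still sees realistic data volumes. The full 132-cell sweep is
the same `run_grid()` call with default arguments. End-to-end recovery
checks halve the generator noise: they are parameter-recovery tests of the
machinery under favourable signal-to-noise, with an internal bar of
micro-F1 ≥ 0.85 for each measure's own-sensor classifier and the
requirement that all-sensor chewing not trail piezo-only chewing by more
than 0.02.

Other numerics: filters use double-precision direct forms with odd
reflection padding of 240 samples (bounded by record length); spectra come
from plain DFTs of de-meaned windows; PCA uses `prcomp` on standardized
training features with zero-variance columns mapped to zero rather than
dropped (keeping column contracts stable); all randomness flows through
explicit integer seeds, and identical seeds give identical scripts,
sessions, splits, searches and grids.

## Known limitations

* Synthetic-only validation; the clean separability of generated events
  inflates absolute scores (see above).
* Device clocks are assumed pre-aligned to session-relative time; no
  cross-sensor synchronization is estimated.
* The piezo band edges and the RIP high-pass cutoff are documented
  defaults, not measured optima; both are configuration.
* Breathing-cycle segmentation and the high-pass interact (a stronger
  filter reshapes minima); the package exposes both parameter sets rather
  than asserting one fixed operating point.
* Hyperparameter search is per-cell, so grid cells are tuned
  independently; sharing a search across cells would be cheaper but
  conflate cells' operating points.
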