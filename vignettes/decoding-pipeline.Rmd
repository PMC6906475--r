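---
title: "Decoding speech from multiunit spiking activity: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding speech from multiunit spiking activity: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(spikespeech)
```

## The problem

Secondary auditory cortex carries a distributed spectrotemporal
representation of complex sounds. Given synchronized recordings of (a)
broadband extracellular voltage from an intracortical multielectrode array
and (b) the audio presented to the subject, the decoding problem is to
regress a time-frequency representation of the audio on binned multiunit
spiking activity, frame by frame, and then to render the predicted
representation back into a waveform whose quality can be measured. This
package implements that pipeline end to end, together with a generative
stand-in for the neural data so the pipeline is testable without animal
recordings.

## Pipeline model and assumptions

The decoding target for frame $t$ is the vector of mel-band powers
$y_t \in \mathbb{R}^{B}$ obtained from an STFT (Hann window, length 2048
samples, centered frames with reflection padding) compressed through a
triangular mel filterbank, standardized per band by subtracting the
training-frame mean. The features are windows of multiunit spike counts
$x_t \in \mathbb{R}^{C(s+1)}$: per channel, crossings of a negative
threshold binned on the same hop grid, with a centered window of span $s$
(the window covers frames $t-s/2, \dots, t+s/2$). The decoder is any map
$\hat{y}_t = f(x_t)$ fit on the training split. Key assumptions:

* the neural-audio alignment is exact (both streams share one clock);
* frames are predicted independently ("bin by bin"), so all temporal
  context must enter through the feature window;
* standardization, noise levels and channel ranking may only use training
  frames (anything else leaks held-out information — the test suite checks
  this invariance explicitly).

Data are split *sequentially* 80/10/10. With pseudorandomly interleaved
sound presentations every sound appears in every split; sequential (rather
than shuffled) splitting keeps temporally adjacent, strongly correlated
frames inside one split.

## Tunable parameters

| Parameter | Units | Default | Notes |
|---|---|---|---|
| `filter_low_hz`, `filter_high_hz` | Hz | 500, 3000 | spike band; grid 100–1000 × 1000–10000 (99 valid pairs) |
| `threshold_factor` | × MAD sigma | 4 | grid 2–5 |
| `dead_time_ms` | ms | 1 | refractory suppression of double counting |
| `span` | frames | 4 | grid 4, 8, 16; Kalman requires 0 |
| `n_channels` | count | all | top-k by training activity, grid 2–96 |
| `n_mels` | bands | 128 | grid 32–256 |
| `hop_ms` | ms | 40 | grid 10–50 |
| `units` | hidden units | 256 | grid 256–2048; tests use 64 for speed |
| `degree` | polynomial | 2 | cascade grid 2–5 |
| `C` | scale on W | 1 | Kalman transition-noise scale, grid 0.1–10 |

The 40 ms hop with 128 bands is the default because coarser mel
compressions, while easier to regress, degrade reconstructed audio even
under a perfect decoder — the package exposes the same "perfect decoder"
bypass (`algorithm = "perfect"`) used to make that trade-off.

## Decoder families

The linear decoders are fitted in closed form: the Wiener filter is
per-band OLS with intercept (rank-deficient feature columns are dropped to
zero rather than failing); the Wiener cascade fits a static polynomial of
the linear output per band; the Kalman filter treats the target vector as
the latent state, with transition and observation models fitted by least
squares and the fitted process-noise covariance scaled by `C`. Scale-aware
ridge terms (1e-6 relative) keep the filter responsive when fitted
covariances degenerate; process noise dominates observation noise so the
filter keeps trusting its observations.

The network decoders have one hidden layer and a linear output, no
dropout: ReLU activations for the dense and simple recurrent nets, tanh
gates for GRU/LSTM. The dense net consumes the flattened window; recurrent
nets consume it as a `span+1`-step sequence of per-channel counts,
predicting from the final hidden state. Training uses minibatches of 128,
learning rate 1e-3, Adam for the dense net and RMSprop for recurrent
nets, early stopping on validation MSE (max 2048 epochs, patience 5,
best-epoch weights restored). Inputs are z-scored and targets scaled by
their per-band training SD internally (undone at prediction time): without
the per-band scale, the summed-MSE loss is dominated by high-power mel
bands and networks plateau below the per-band OLS solution on the
equal-band-weight correlation metric. The engine is written directly on
base matrix operations; its gradients are verified against numerical
differentiation in the test suite.

## What the synthetic generator emulates

`synth_session()` produces a passive-listening session: word-like tokens
(harmonic sources with formant-like resonance sweeps, distinct durations
and spectral regions) played in seeded pseudorandom order, 40 repetitions
each by default, at 1 s intervals, with audio and 16 channels of 30 kS/s
broadband voltage. Each informative channel has a smooth spectrotemporal
receptive field (an excitatory Gaussian bump in band × lag, plus a weaker
inhibitory sidelobe half the mel axis away); its firing rate is

$$ r_c(t) = \big[\, b_c + g \textstyle\sum_{b,\ell} W_{cb\ell}
   \, P_b(t-\ell) \,\big]_+ $$

evaluated on a 10 ms grid (mel power $P$ normalized by its session RMS),
driving an inhomogeneous Poisson process at full sample-rate resolution.
Spikes superimpose a biphasic, trough-negative template (−80 µV) on
Gaussian-plus-pink noise (10 µV SD, half pink). Defaults (gain 60 s⁻¹,
baseline 10 s⁻¹) give ~50–100 crossings/s on informative channels —
realistic multiunit rates at a high signal-to-noise operating point.

The half-wave rectification is the generator's single nonlinearity. With
the default baseline the drive rarely clips and linear decoding is nearly
sufficient; with baseline 0 ("rectified encoding") half the drive range is
clipped, the counts-to-mel inverse becomes context dependent, and recurrent
networks reliably beat the Wiener filter — the package's qualitative
reproduction of the nonlinear-over-linear ordering of decoder families.

What the generator does **not** emulate: adaptation, refractory
interactions, correlated noise across channels, non-Poisson firing
statistics, movement or acoustic artifacts, electrode drift across
sessions, and any realistic cortical transformation beyond one static
rectified STRF per channel. Passing tests on synthetic sessions therefore
demonstrates the *pipeline's* correctness and sensitivity, not performance
to be expected on cortical data.

## Numerical choices

* STFT: Hann (periodic) window, centered frames, reflection padding,
  `1 + floor(n/hop)` frames; Griffin–Lim uses 64 iterations from seeded
  uniform random phase, and its spectral-convergence error is checked to be
  non-increasing.
* Mel filterbank: triangular on the HTK mel scale, area-normalized rows;
  inversion is the SVD pseudo-inverse with negative values clipped at zero
  on both sides (power cannot be negative).
* Elliptic bandpass: 0.1 dB passband ripple, 40 dB stopband attenuation,
  applied forward-backward (zero phase) so crossing times are not shifted.
* MAD noise estimate uses the Gaussian consistency constant 0.6745 and
  recenters by the median.
* NCF pitch: 50–400 Hz search, 40 ms frames, voicing when the NCF peak
  ≥ 0.6; among near-maximal peaks the shortest lag wins (octave-error
  guard), with parabolic refinement.
* K-weighting for loudness is designed at the native sample rate by
  tan-prewarped bilinear transform of the standard's prototypes; the design
  reproduces the printed 48 kHz coefficients and scores a full-scale
  997 Hz sine at −3.01 LUFS.
* ESTOI: 10 kHz internal rate, 15 third-octave bands from 150 Hz, 384 ms
  (30-frame) segments, 40 dB silent-frame removal.
* STMI: 128-channel log-frequency spectrogram, Gaussian modulation filters
  at rates {2,4,8,16,32} Hz × scales {0.25,…,8} cyc/oct — a compact,
  linear-in-magnitude stand-in for full auditory-model front ends, chosen
  so the closed-form identities (identical → 1, silent or doubled → 0)
  hold exactly.

## Design decisions on open points

* Targets are linear mel power; a dB option exists (`db = TRUE`) but
  defaults off.
* Crossings are detected on the filtered trace at the full sampling rate
  (filtering precedes detection; "full-broadband" is read as full rate).
* Inter-trial silence is excluded: only labeled trial spans enter the
  dataset, trimmed to whole hops, and the sequential split operates on the
  concatenated frame timeline (it may split within a trial).
* The Kalman `C` multiplies the fitted transition-noise covariance, and
  recurrent decoders are windowed per prediction (not stateful across
  bins), matching the centered-window feature definition.
* The common correlation `r_w` in the multisample test is the
  sample-size-weighted mean in z-space, back-transformed; Conover pairwise
  p-values are Holm-adjusted.

## Problem sizes used by the tests

The shipped tests run the full pipeline at desk scale, chosen to exercise
every code path in a few minutes of CPU: the linear-recovery check uses the
default session (3 tokens × 40 reps, 16 channels, ~175 s of 30 kS/s data)
with 32 mel bands; the paired LSTM-vs-Wiener comparison uses 20 reps per
token and 64 hidden units over 5 seeds; statistical calibration uses 2000
null simulations of 10 blocks × 3 models. Network sizes in the paper-scale
grid (256–2048 units, 128 bands, 96 channels) are supported but not
exercised by default.

## Known limitations

* The NN engine is CPU-bound plain R; paper-scale grids (thousands of
  models, 2048-unit networks) are out of its intended range.
* ESTOI follows the reference construction but has not been calibrated
  against listener data; treat scores as relative, not absolute.
* The Kalman filter initializes its state at zero (standardized target
  mean) rather than at a ground-truth frame, so its first few frames are
  transient.
* `grid_search()` runs sequentially; it records per-run failures rather
  than parallelizing.
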