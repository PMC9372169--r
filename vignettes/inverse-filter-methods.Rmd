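---
title: "Restoring infraslow EEG activity by deconvolution: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Restoring infraslow EEG activity by deconvolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isafilter)
```

## The model

An AC-coupled EEG acquisition chain is treated as a linear
time-invariant (LTI) system: the recorded output is the convolution of
the true input with the system's unit impulse response (UIR),
`y = x * h`. Everything in this package follows from two facts about
LTI systems:

* the UIR is the derivative of the step response, so feeding the system
  a step (or its built-in square-wave calibration signal, which is a
  train of steps) and differentiating the measured response
  characterizes `h` without knowing anything about the hardware; and
* convolution is invertible by polynomial long division, so a recording
  can be deconvolved by `h` to recover the input — in particular the
  sub-0.1 Hz infraslow band (ISA) that the system's high-pass input
  stage attenuates.

The assumptions are: linearity (no amplifier saturation — the forward
model's `clip_range` exists precisely to create the pathological case),
time invariance (the amplifier is not being reconfigured mid-recording),
and stationarity of the UIR between characterization and use (same
amplifier model and settings).

## UIR characterization

`characterize_uir()` composes four steps, each exposed individually.

**Onset detection.** Onsets are 50%-of-step-height crossings, with the
step height measured from the *resting baseline* — estimated by the
median — to the extreme in the requested polarity, and refined by
linear interpolation between the bracketing samples. The median
reference matters because an AC-coupled recording of a square wave is
bipolar: its global minimum is the opposite-polarity transition, not
the pre-step level. A Schmitt trigger (a crossing only counts after
the signal has dipped below the 25% level since the last accepted
onset) rejects re-crossings that occur when a decaying response hovers
near the threshold under noise.

**Segment averaging.** For calibration squares, three onset-aligned
step responses are averaged (the default `n_average = 3`), and the
pre-onset mean is subtracted from each segment so the polynomial models
the response rather than an offset. Averaging reduces noise variance
by the number of segments.

**Polynomial fit.** The averaged response is fitted with a 9th-order
least-squares polynomial on a *normalized* time axis (centred, scaled
to `[-1, 1]`). At order 9 a raw-seconds Vandermonde matrix over
several hundred samples is numerically singular; the normalized axis
keeps it well conditioned, and the derivative is taken analytically
with the chain rule through the normalization. The default fit window
runs from the onset to where the smoothed response magnitude settles
within 1% of the initial jump (or to the next onset / end of segment,
whichever is earlier); the settle rule keeps the UIR — whose length
equals the window — as short as the data allow, which bounds the cost
of deconvolution.

**Discretization of the derivative.** The step response of a high-pass
system jumps discontinuously at the onset and then decays; its
derivative is an impulse plus a smooth tail. Discretely, the first
tap carries the jump as a one-sample impulse, `h[1] = p(t0) * rate`,
and the remaining taps are the scaled differences of the fit,
`h[n] = (p(t_n) - p(t_(n-1))) * rate`, which converge to the analytic
derivative. This construction makes the convolution of a step with
`h / rate` reproduce the fitted response exactly, so the
self-consistency of the whole loop is limited only by the fit residual.
A trailing tail below `1e-6` of the peak magnitude is trimmed.

**Normalization and self-check.** Units are arbitrary throughout (as
they are for EEG amplitudes), so the output scale is anchored by a
self-check rather than by a hardware gain: deconvolving the fitted
step response by `h` must yield a flat plateau, and `norm` is chosen so
that this plateau equals the measured jump height — i.e. unity passband
gain is assumed. `characterize_uir()` then repeats the deconvolution
on the *measured* (not fitted) averaged step and reports two metrics:
plateau peak-to-peak flatness relative to the jump, and plateau slope
per second. The gate is `flatness < 0.2` by default. The margin is
deliberate: the 1%-settle window rule leaves up to ~1% of the response
tail unmodelled, and that truncation error integrates during
deconvolution into a slow plateau sag of roughly 5% on a clean
first-order 0.1 Hz chain and ~13% when the step was recorded at a
linear SNR of 100. A plateau within 20% peak-to-peak still
unambiguously "resembles a step", whereas a mischaracterized UIR
(wrong mode, clipped or saturated recording) fails the gate by an
order of magnitude. The sag can be reduced by fitting deeper (a
smaller settle fraction) at the price of a longer UIR.

Because the UIR is stored together with its continuous fit,
`uir_at_rate()` re-derives it exactly at any sampling rate — no
polyphase approximation of the impulse-like first tap is ever needed,
and a system characterized at 1000 samples/s can filter recordings
analyzed at 256 samples/s.

## The inverse filter

`deconvolve()` performs time-domain long division as recursive inverse
filtering (`x[n] = (y[n] - sum h[k] x[n-k]) / h[1]`), which is
algebraically identical to the quotient of polynomial division and runs
at C speed via `stats::filter()`. The quotient has
`length(y) - length(h) + 1` valid samples; the output is re-padded to
the input length by holding the last value, so sample-time alignment
with the input is preserved for overlays, and the `n_valid` attribute
reports the boundary. Spectral comparisons in the validation suite are
computed over the valid region. Everything is double precision — the
drift discussed next is an accumulation of rounding error, so precision
is never reduced.

Two guards reflect the drift phenomenology. Deconvolution can
introduce a triangular drift at `1 / (2 × epoch length)` Hz
(`drift_frequency()`); reconstructed signals are therefore high-pass
filtered at 0.005 Hz (2nd-order Butterworth) before use, and epochs
must span at least `min_periods = 3` periods of the lowest frequency of
interest (`min_length_for()`: 600 s for 0.005 Hz) so the drift cannot
be confused with signal. The drift filter is applied *zero-phase*
(forward–backward, with odd-reflection padding spanning several filter
time constants so no startup transient enters the epoch): a causal
filter here would re-introduce exactly the phase distortion the
deconvolution has just corrected. The choice is switchable
(`drift_zero_phase = FALSE`) for strictly causal pipelines.

`chunked_inverse_filter()` reconstructs long recordings as overlapping
clips that are inverse filtered independently and blended with a
raised-cosine cross-fade. Each chunk must satisfy the minimum-length
rule, and the overlap must exceed three UIR durations so the edge-held
region of one chunk never reaches the blend at full weight; interior
agreement with the whole-signal result is within 5% RMS in the test
conditions (1800 s mixed sine, 600 s chunks, 120 s overlap).

## The simulated recording chain

`recording_chain()` models the acquisition hardware as causal filters
(default: one first-order RC high-pass at 0.1 Hz, matching a typical
clinical broadband of 0.1–344 Hz), a gain, optional hard clipping and
optional Gaussian noise. Causality is essential — the phase-distortion
results only exist because real amplifiers are causal — and filter
state is initialized to steady state for the pre-signal baseline so
simulations do not begin with an artificial transient. The chain is a
test scaffold, not a claim about any particular instrument: the
characterization method is non-parametric by design, and the
first-order default merely provides a closed-form oracle
(`analytic_attenuation()`, `analytic_phase_lead()`) for testing.

## Synthetic signals and what passing tests show

The generators reproduce the validation inputs: step, double step
(two 10 s pulses in 60 s), step with a 10 Hz sine overlay, a mixed
sine with components at 0.01, 0.05, 0.07, 0.15, 0.2, 1, 6 and 10 Hz
(amplitudes default to 1 and phases to 0, since only the frequency
list is prescribed), a 50%-duty calibration square, and a surrogate
seizure. Noise is specified as a linear variance ratio (SNR), the
simplest reproducible convention; `snr_db_to_linear()` converts from
dB. All stochastic generators take explicit seeds and are exact
functions of their arguments.

The surrogate seizure emulates the qualitative anatomy of a
DC-amplifier seizure recording — a sigmoid-ramped DC shift beginning
just before onset, a wind-shaped oscillatory burst during the seizure,
a biphasic two-exponential spreading-depolarization wave after offset,
and white baseline noise — with ground-truth components returned
separately. Defaults (100 s seizure in a 900 s epoch, unit-magnitude
downward shift, 8 Hz burst, 20 s post-ictal time constant, noise SD
0.02) were chosen once as a plausible intracranial scenario. What it
deliberately does not model: colored background EEG, electrode drift
and movement artifacts, multi-channel structure, or any biophysics of
spreading depolarization. Passing tests therefore demonstrate that
the *method* restores sub-0.1 Hz structure distorted by a known LTI
chain; they do not certify performance against real-world artifacts,
which the method would reconstruct just as faithfully as physiology.

## Numerical and design choices

* **Downsampling** (`downsample()`): zero-phase 8th-order Butterworth
  anti-alias at 0.45 × target rate, then cubic-spline evaluation on the
  new time grid, staged by factors of at most 10 so the digital filter
  stays well conditioned. For integer ratios the new grid falls on
  original sample instants and interpolation is exact. This design
  was chosen after the polyphase resampler available to us showed a
  measured ~15% passband amplitude error on the relevant ratios; the
  present scheme preserves a sub-Nyquist sine's amplitude within 1%.
* **Spectra** (`amplitude_spectrum()`): single-sided, Hann-windowed
  with coherent-gain correction so a bin-centred sine of amplitude A
  peaks at ~A; `window = "none"` gives Parseval-consistent raw
  amplitudes. Phase convention: with kernel `exp(-2πift)`, `cos` has
  phase 0 and `sin` has `-π/2`.
* **Phase comparisons** (`fidelity_report()`): Pearson correlation of
  *wrapped* phases at bins whose input amplitude exceeds 1% of the
  spectrum maximum. For sparse synthetic spectra the above-floor phase
  sequence jumps by exactly π between component clusters — the branch
  point of unwrapping — and unwrapping was observed to send two nearly
  identical spectra to divergent sequences (r ≈ −0.13 for an excellent
  reconstruction). Wrapped phases at signal-bearing bins are
  well-defined and give the expected ordering robustly; circular
  statistics would be the fully principled alternative and are noted
  as such.
* **Morlet scalogram** (`morlet_scalogram()`): 6 cycles by default
  (a conventional compromise between time and frequency resolution),
  wavelets normalized to unit response to a complex exponential so a
  unit sine yields ridge power ~1, and a per-frequency cone of
  influence of 3.5 Gaussian widths reported via `edge_samples` /
  `scalogram_interior()`.
* **Degenerate inputs**: constant step responses flag the UIR as
  degenerate (`h[1] ≈ 0`) and refuse deconvolution; zero-variance
  signals make correlations error rather than return `NaN`; upsampling
  requests, Nyquist violations, overlapping pulse intervals and
  non-uniform text time bases are rejected with specific errors.
* **Ties and windows**: epochs are half-open `[start, end)`; the step
  sample at the onset instant belongs to the post-step level.

## Problem sizes in the test suite

The suite validates at desk scale, chosen so the full run stays in the
tens of seconds: UIR characterization from 30 s steps at 50–1000
samples/s; the 60 s double-step round trip at 1000 samples/s; the
600 s mixed-sine loop at 100 samples/s; noise Monte Carlo (20 seeds ×
3 SNRs) analyzed at 256 samples/s — the rate the clinical workflow
itself downsamples to; chunking on a 1800 s record at 50 samples/s;
and the 900 s surrogate seizure at 100 samples/s with wavelet analysis
at 25 samples/s. The brute-force deconvolution oracle (a
lower-triangular Toeplitz solve) uses 100 random kernel/signal pairs
with n ≤ 256; kernels are drawn impulse-dominated
(`|h[1]| > Σ|h[rest]|`), because the inverse recursion of an arbitrary
random kernel is exponentially unstable and *no* algorithm agrees with
anything in double precision there — physical UIRs of high-pass chains
are impulse-dominated in exactly this sense.

## Known limitations

* The reconstruction scale assumes unity passband gain; absolute
  calibration would need a reference amplitude.
* The plateau sag from the 1%-settle truncation (see above) bounds
  reconstruction flatness over intervals much longer than the UIR.
* Chunked reconstruction blends away very-low-frequency content below
  each chunk's own drift guard; frequencies below
  `min_periods / chunk_len` are not trustworthy in chunked output.
* EDF export quantizes to 16 bits of each channel's dynamic range;
  internal processing is double precision throughout.
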