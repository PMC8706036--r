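---
title: "Contact pressure and PPG morphology: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contact pressure and PPG morphology: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppgpress)
```

## The problem

Reflectance photoplethysmography (PPG) sensors — the kind found in
wrist-worn wearables — press against the tissue they measure. The contact
pressure (CP) exerted by the sensor changes the optical coupling and, more
importantly, the transmural load on the vessel underneath: light pressure
leaves the vessel wall pre-stressed and stiff, pressure near the vessel's
mean internal pressure minimises wall stress and maximises pulsatile
volume change, and higher pressure progressively occludes the vessel until
the pulsatile signal vanishes. There is therefore an *optimum* contact
pressure for signal quality, and every morphological pulse feature is
potentially biased by CP.

`ppgpress` provides a tested pipeline for quantifying these effects:

1. a synthetic-data generator that stands in for a pulsatile tissue-vessel
   phantom pressed by a slowly descending sensor;
2. signal conditioning (4th-order Butterworth low-pass, 12 Hz, zero-phase);
3. per-second SNR tracking against CP with optimum-pressure detection;
4. automatic isolation of the pulsatile segment via a rectified-envelope
   procedure;
5. cardiac-cycle and tangent-intersection (TI) fiducial detection;
6. extraction of 17 morphological features per cycle;
7. Spearman-based ranking of feature robustness to CP.

## The simulated world

The generator emulates a fixed experimental protocol: a pump drives a
60 BPM (1 Hz) bell-shaped pressure pulse through an artificial vessel at
3 mm depth; a 1 cm^2 dual-wavelength (red/infrared) sensor descends into
the tissue at 0.03 mm/s until the vessel is fully occluded; PPG, load-cell
force and inline pressure are sampled at 1 kHz. Four blood-pressure states
are available (`pressure_states()`), whose MAP values follow the
one-third-pulse-pressure rule `MAP = DBP + (SBP - DBP)/3`.

Key modelling choices (each a package design decision, since the physical
system constrains but does not dictate them):

* **Bell pulse.** A periodised Gaussian, min-max normalised so the foot is
  exactly 0 and the mode exactly 1 (`bell_pulse()`). Width default 0.25 of
  the period. Any smooth unimodal profile satisfies the contract; the
  choice is recorded in the configuration.
* **Contact mechanics.** Hookean: force is linear in indentation, and the
  stiffness default is chosen so the occlusion pressure is reached at
  exactly the vessel depth (3 mm). Force converts to pressure by
  `P = F/(A * 133)` with `A` the sensor area (`force_to_mmHg()`; a
  high-precision mode uses 133.322 Pa/mmHg).
* **Amplitude transfer** (`contact_transfer()`). The pulsatile gain is the
  product of (i) an optical-coupling term `1 - exp(-cp/2 mmHg)` that
  saturates within a few mmHg of touch-down, and (ii) a compliance term
  that drifts gently upward with load (0.6 -> 1.0 of its plateau), peaks
  exponentially (scales 1.5 / 8 mmHg) at the transmural-equilibrium
  optimum, and is renormalised to reach exactly zero at the occlusion
  pressure. The optimum defaults to the state's MAP mapped linearly into
  the 35-48 mmHg band in which optimal sensor pressures are observed
  empirically (the tissue attenuates the external pressure, so the optimum
  at the surface is far below MAP itself); occlusion defaults to
  20 mmHg above the optimum. The sharp (1.5 mmHg) rise scale reflects the
  disappearance of the exponential stiffening of the wall exactly at
  transmural equilibrium; it also makes "the" optimum a well-posed
  quantity at the generator's noise level — with a broad plateau the
  per-window SNR argmax would be dominated by estimator noise, which is
  visible in practice as multi-mmHg replica scatter.
* **Noise.** White Gaussian, default SD 0.02 V against a 1 V pulse at the
  optimum. This puts the peak per-second SNR near 26 dB, the level
  reported for phantom measurements of this kind. The red channel gets a
  lower pulsatile gain (0.8 vs 1.0), hence ~2.5 dB lower SNR than
  infrared. No motion artefact or respiratory modulation is simulated
  (absent from the emulated protocol), no finite-element tissue mechanics,
  no photon transport.
* **Ground truth.** The truth block stores exact cycle onset times,
  contact/optimum/occlusion times and the *pulsatile window*, defined as
  the span where the pulsatile gain exceeds 5% of its maximum — the
  pulsatile component is effectively extinguished before the occlusion
  pressure itself is reached, and that extinction is what a segmentation
  algorithm can recover. The analysis pipeline never reads the truth
  block.

What a green test does and does not establish: the generator reproduces
the *structure* of the physical experiment (ramped CP, amplitude
resonance, occlusion, two channels, four BP states) but not the optics or
mechanics of any real phantom; absolute SNR values and optimum pressures
are calibration inputs, not predictions. Recovery tests therefore validate
the *pipeline* (does it find what was configured?), not the physics.

## Signal conditioning

All analysis channels pass through a 4th-order Butterworth low-pass at
12 Hz applied forward-backward (`lowpass_zero_phase()`), giving zero phase
and the squared single-pass magnitude. The Butterworth family is chosen as
the standard maximally flat IIR for PPG work; coefficients come from the
bilinear transform with prewarping and are verified in the tests against
the analytic magnitude response. Signals are never resampled, preserving
temporal detail for the features. Edge transients are suppressed by odd
extension with a padding length of `6 fs / cutoff` samples.

Envelope work uses linear-phase windowed-sinc FIR smoothers with
group-delay compensation (`fir_lowpass()`): 0.5 Hz cut-off at order
`5 * fs` for the envelope of the rectified signal, 0.1 Hz at order
`10 * fs` for its derivative. The heavy orders are deliberate — at 1 kHz
they give multi-second smoothing, which is what makes the envelope
geometry (below) usable. Odd orders are promoted to even so the group
delay is an integer.

## SNR against contact pressure

`snr_db()` follows the periodogram convention popularised by MATLAB's
`snr()`: Kaiser window with beta = 38 (sidelobes below double precision,
so leakage never contaminates the noise estimate), DC lobe excluded, the
fundamental is the largest remaining peak with its power summed over its
main lobe (bounded by local minima), the first six harmonics are likewise
excluded, and the noise power is the mean of the remaining bins scaled to
the full non-DC bandwidth. The mean is removed before windowing, otherwise
a volt-scale DC baseline smears into a 1 Hz fundamental at 1 s windows.

The SNR is computed on the **unfiltered** channel by default: the analysis
treats everything the 12 Hz filter would remove as true noise, so that
noise must be allowed to count. (A `filtered = TRUE` switch computes the
in-band variant; note that at 1 s windows and a 12 Hz band only a handful
of periodogram bins estimate the noise, which makes the per-window SNR
fluctuate by ~2 dB and the argmax-based optimum correspondingly unstable.)

`snr_trace()` evaluates one window per whole second and pairs it with the
mean CP in that window; `find_optimum()` returns the global maximum
(earliest window on ties). Windows with a constant signal (noiseless
occluded baseline) are reported as `-Inf`: total signal loss.

## Pulsatile-segment isolation

Within the contact window (first positive force to maximum force), the
12 Hz-filtered signal is median-centred, rectified and smoothed into an
envelope; the envelope's derivative is smoothed at 0.1 Hz; both curves are
min-max normalised over the contact window. The segment start is the first
intersection of the two normalised curves (sign change in either
direction — the published figure this reproduces marks the start at the
first intersection); the end is the first envelope onset (local minimum
dominating a +/-0.5 s neighbourhood, first sample of flat runs) after the
global minimum of the smoothed derivative, clipped to the contact window.
Records whose pulse-band (0.5-3 Hz) power fraction is below 0.5 are
rejected as non-pulsatile before any envelope work.

Numerical notes: the rectification baseline is the window median (a
DC-positive PPG would otherwise rectify to itself); normalisation is over
the contact window only; the end edge sits where the decaying envelope
meets the noise floor, so its location is intrinsically noise-level
dependent (a 5x noise increase moves it by a few seconds of a ~90 s
window — the start edge is stable to well under half a second).

## Cycles, TI points and features

Cardiac cycles are detected with an adaptive-threshold derivative
detector: upstrokes where the slope exceeds 40% of its local (~2 s)
rolling maximum, a 0.3 s refractory period, onsets as the signal minimum
in a 0.5 s look-back, peaks as the maximum between consecutive onsets.
Incomplete edge cycles are discarded. Slopes are estimated by central
differences over a +/-40 ms window, matched to the 12 Hz band — one-sample
differences at 1 kHz are dominated by residual in-band noise and blur the
max-slope fiducial and its amplitude (F3). Detection is invariant to
amplitude scaling.

The TI point intersects the tangent at the maximum-slope point with the
horizontal tangent at the pulse valley: `ti = t_m - (y_m - y_v)/s_m`. The
construction is exact for locally quadratic upstrokes and is clipped (with
a warning) at the onset time if the geometry degenerates.

The 17 features (`feature_classes()` lists ids, classes and units) follow
the standard morphological set: TI-to-TI duration and area (F1, F4),
amplitudes (F2, F3), systolic/diastolic phase areas (F5, F6), region
centroids of pulse/systolic/diastolic regions (F7-F12), pulse width
F13 = F11 - F9, rise/decay times (F14, F15) and slope angles
F16 = atan(F2/F14), F17 = atan(F2/F15). Conventions adopted where the
source material is ambiguous:

* areas are in V s and x-centroids in s (the dimensionally coherent
  reading of mixed printed units);
* the area/centroid baseline is the cycle's onset amplitude, negative
  excursions clipped;
* x-centroids are reported **relative to the cycle onset**: on a
  continuous pressure-ramp protocol an absolute time coordinate is a
  monotone proxy for elapsed time and hence CP, which would make the
  "temporal" features the most CP-correlated by construction;
* y-centroids are absolute voltages (the onset baseline is recorded);
* angles use raw (V, s) ratios, as conventionally printed.

## Feature ranking

`spearman_rho()` is the Pearson correlation of mid-ranks (average ranks on
ties), implemented explicitly and tested to 1e-12 against a brute-force
rank-then-correlate oracle. Each feature is correlated against the
cycle-mean CP (the within-cycle CP value is not uniquely defined by the
protocol; the cycle mean is used); `rank_features()` orders features by
ascending |rho| — the front of the ordering is least affected by contact
pressure. Constant features are flagged and sorted last; ties break by
feature index. No p-values or multiple-testing corrections are computed:
the ordering itself is the deliverable. `class_summary()` aggregates rank
positions by class and flags `temporal_robust` when the temporal median
rank is below the amplitude median rank.

The qualitative finding this reproduces: with pulse timing CP-invariant
and amplitude CP-modulated, temporal features (durations, x-centroids)
cluster at the robust end of the ordering and amplitude features (areas,
voltages, y-centroids) at the affected end, across states, replicas and
wavelengths.

## Known limitations

* The generator's transfer function is phenomenological; its plateau,
  rise/fall scales and coupling scale are plausibility choices, not fits.
* HDF5 record export is not provided (no HDF5 R binding in the supported
  dependency set); CSV (wide canonical, long-form export) is.
* One contact ramp per record; no multi-segment handling.
* Second-derivative (acceleration-wave) features are out of scope.
* The end edge of the pulsatile segment is noise-level dependent (see
  above); treat sub-second comparisons of that edge across noise levels
  as meaningless.

## A worked run

```{r example, eval = FALSE}
rec <- simulate_recording(generator_config(state = "normotensive",
                                           seed = 3))
an <- run_pipeline(rec, replica = 1)
an$ir$optimum          # ~26.5 dB near the configured optimum pressure
head(an$ir$features)   # 17 features + cycle-mean contact pressure
an$ir$ranking          # ascending-|rho| ordering, temporal features first
class_summary(list(an$ir$ranking, an$red$ranking))
```
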