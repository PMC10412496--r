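---
title: "Detecting walking bouts from foot-worn inertial sensors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting walking bouts from foot-worn inertial sensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitbouts)
```

## The problem

A foot-mounted IMU records 3-axis angular velocity and acceleration
continuously, but most of a free-living recording is not walking. Before
any gait parameter (speed, cadence, stride length) can be computed, the
walking bouts — contiguous episodes of locomotion — must be located. The
difficulty is that peak-based stride detection on a single gyroscope axis
is very sensitive to how the sensor is mounted, while free-living data are
full of non-gait movements that mimic single steps.

`gaitbouts` addresses both problems the same way the best foot-sensor
detectors do: it operates on the *norm* of the 3-axis signal, which is
invariant to any fixed mounting rotation, and it separates walking from
non-walking with subject-adaptive amplitude thresholds plus a
cadence-adaptive grouping rule.

## The processing model

### Peak enhancement

The chain `enhance()` applies is, in order:

1. **Norm.** `compute_norm()` — the Euclidean norm of the gyroscope
   (deg/s) or accelerometer (g) sample vectors. For any rotation matrix
   $R$, $\lVert R\,\omega \rVert = \lVert \omega \rVert$, which is the
   entire basis of the calibration-free claim; the test suite asserts
   bit-equal detections under 20 random mounting rotations.
2. **Downsampling to 40 Hz.** Stride content lives well below 5 Hz, so a
   40 Hz analysis rate loses nothing and makes long recordings cheap to
   process. The resampler anti-alias filters (zero-phase FIR, cutoff at
   90 % of the target Nyquist) and then interpolates onto the analysis
   grid.
3. **Detrend + zero-phase low-pass.** A least-squares linear detrend
   removes slow drift, then a Hamming-window FIR low-pass (120
   coefficients, cutoff 3.2 Hz) removes high-frequency content. The filter
   is applied forward and backward, so the net phase is zero and peak
   locations do not move. Because the filter is FIR, forward–backward
   application equals a single convolution with the filter's
   autocorrelation; the package implements it that way, with the filter
   normalised to exact unit DC gain and symmetric reflection padding so
   boundaries create no spurious peaks.
4. **Single-scale CWT.** Correlation with a second-derivative-of-Gaussian
   (gaus2) wavelet dilated to scale 15 at 40 Hz. This is simultaneously a
   smoother and a differentiator: each smooth mid-swing bump becomes one
   positive peak at the bump centre, while slow baselines vanish. The
   amplitude convention is the classic $a^{-1/2}$ correlation with the
   unit-energy wavelet (the convention of the widely used MATLAB and
   PyWavelets `cwt` implementations); at scale 15 it amplifies
   stride-rate content roughly five-fold, which is what makes the
   100 deg/s fixed threshold a *conservative* cut relative to typical
   mid-swing peaks of several hundred deg/s. If the analysis rate is
   changed, the scale is rescaled proportionally so the passband stays
   centred near stride frequency (≈ 0.85 Hz at the defaults).
5. **Savitzky–Golay smoothing.** A linear fit over an 11-sample (0.275 s)
   window — slight smoothing, shorter than any plausible stride, that
   reproduces ramps exactly.

Two details of this chain were genuinely open design choices: the detrend
flavour (least-squares linear over the whole series, the conventional
default) and the Savitzky–Golay window (11 samples; "slight" smoothing
demands a window well under the shortest stride period). Both are exposed
in `enhancement_params()`.

### Peak selection

`detect_candidate_peaks()` takes every strict local maximum (plateaus
resolve to their centre sample); the enhancement chain already band-limits
the signal, so no minimum-distance constraint is needed. Three selection
rules then apply, all with inclusive (`>=`) comparisons so tie behaviour
is deterministic:

* **Fixed** (`select_fixed()`): amplitude ≥ 100 deg/s (gyro) or 0.5 g
  (acc). Very sensitive, not specific: any movement with enough energy in
  the stride band passes.
* **Adaptive** (`select_adaptive()`): the fixed cut first, then a
  percentile (default 10) of the surviving amplitude distribution,
  computed with type-7 (linear interpolation) quantiles. The threshold is
  subject-specific and, by construction, never below the fixed one. It is
  computed once per recording per foot, not per bout — one amplitude
  distribution per sensor.
* **Hilbert** (`select_hilbert()`): the analytic-signal envelope of the
  enhanced signal marks candidate walking periods wherever it stays at or
  above the fixed threshold for at least 1 s (sub-threshold gaps shorter
  than 3 s merged); the threshold is then a percentile (default 1) of the
  in-period peak amplitudes. The envelope pre-selection makes this the
  most restrictive method, so its percentile must stay low.

The exact construction of the Hilbert pre-selection (envelope threshold,
minimum duration, gap merging) is a design choice of this package — the
operational reading that reproduces the intended "pre-selected walking
periods" behaviour — and all three constants are configurable in
`threshold_spec()`.

### Bout grouping

`group_events()` scans the selected event times left to right. The current
bout's gap limit is 5 s (single sensor) or 3.5 s (dual) until the bout
holds two events; afterwards it is `update_offset` plus the mean
intra-bout inter-event duration, recomputed after every accepted event and
capped at the initial value. The offset (3 s single, 1.5 s dual) makes the
limit track cadence: a slow walker with 3 s strides keeps a 5 s allowance
(40 steps/min is the slowest supported cadence), a brisk walker is held to
≈ 4 s so unrelated movements do not attach to the bout. The cap resolves
an ambiguity between "initialised at 5 s" and "maximum 5 s between peaks":
without it a 3 s-stride walker would get a 6 s allowance, contradicting
the stated maximum, so the cap is adopted. Comparisons are inclusive.

`filter_true_locomotion()` then drops episodes with fewer than 5 merged
steps (dual) or 3 same-foot strides (single). The five-step rule has no
exact single-foot analogue; 3 same-foot strides is the smallest count that
implies at least five steps, and the value is configurable
(`grouping_params(min_events=)`).

Bout boundaries equal the first and last member event time. This is the
simplest defensible convention and carries a documented bias of about half
a stride at each edge relative to references that see the true movement
onset — visible as a ~2 % per-sample sensitivity loss on clean synthetic
data.

### Evaluation

`bouts_to_labels()` rasterises bouts to per-sample binary labels on
half-open `[start, end)` intervals (adjacent bouts tile without double
counting), by default at the 40 Hz analysis rate; a per-second
majority-vote mode (`collapse_per_second()`) is provided for coarser
evaluation granularity. `confusion_metrics()` uses the standard
definitions — sensitivity TP/(TP+FN), specificity TN/(TN+FP), accuracy
(TP+TN)/total, precision TP/(TP+FP) — with zero-denominator rates reported
as `NaN`, never 0. `roc_sweep()` re-runs the full pipeline per percentile
over a grid defaulting to {1, 2.5, 5, …, 50}.

## The synthetic data generator

`simulate_recording()` emulates the features of free-living foot-IMU data
that the detector actually relies on, with ground truth:

* **Walking bouts** of cyclic strides: each stride contributes a dominant
  smooth mid-swing bump on one gyroscope axis (σ = 0.11 × stride
  duration), with smaller heel-strike/toe-off ripples on the other axes,
  and heel-strike loading on the accelerometer (a broad 1.5–2.5 g bump
  plus a sharp transient) riding on the 1 g gravity baseline. Default
  stride durations are 0.9–1.4 s (a slow-walker preset extends to 3 s) and
  mid-swing amplitudes 250–500 deg/s, drawn as a per-bout mean with ±10 %
  per-stride jitter — a walker holds roughly constant intensity within a
  bout.
* **Rest periods** of white sensor noise (5 deg/s), at least 8 s long so
  bouts are genuinely separate.
* **Artifacts**: isolated 0.5–2 s shakes (default 2/min) with 1.5–3 Hz
  oscillation — brisk enough to be non-gait, yet passing the 3.2 Hz
  low-pass — whose enhanced amplitudes straddle the fixed threshold while
  staying mostly below the adaptive one. This is what makes the fixed
  vs. adaptive contrast observable.
* A **random fixed mounting rotation** applied to every simulated sensor,
  so orientation invariance is exercised on every run. Bilateral mode
  generates a synchronized left/right pair with left strides offset by
  half a stride and an optional amplitude asymmetry ratio.

Everything is deterministic given the seed. Bout lengths derive from a
walking-time fraction (default 0.55) of the recording, or from an explicit
`strides_per_bout` when a scenario needs an exact stride count (the toy
fixtures use this).

What the generator does *not* emulate: biomechanically valid waveforms,
gravity leakage into the gyroscope, sensor drift and saturation,
pathological gait beyond slow/asymmetric presets, and sustained non-gait
cyclic activities (stair descent, cycling). Passing tests therefore show
that the implementation realises the stated algorithm and its qualitative
behaviour — they are not evidence about performance on real recordings.

The `artifact_storm` fixture deserves a note: random shake placement makes
the fixed-vs-adaptive false-positive contrast depend on where shakes land
relative to bouts, so the fixture constructs it deterministically — three
1.5 Hz, 200 deg/s shakes 3.5 s apart in the longest rest. The spacing is
under the 5 s gap limit, so the fixed method chains them into a spurious
bout; their enhanced amplitude sits above the fixed threshold but below
every stride peak, and with 3 shake peaks against 20 stride peaks the
10th-percentile rank lands strictly above all three, so the adaptive
method provably prunes them.

## Numerical choices and degenerate inputs

* Percentiles: type-7 quantiles (linear interpolation between closest
  ranks) everywhere.
* All filtering and the CWT use symmetric reflection padding (triangular
  folding, so pads longer than the series are valid).
* The low-pass stage refuses series shorter than three filter lengths
  (9 s at the defaults) — below that, edge effects would dominate.
* An empty selected-peak set yields an empty bout list; an all-zero
  recording yields an all-zero enhanced signal; a reference label vector
  with one class absent reports the undefined rates as `NaN`.
* Exact threshold ties are kept (inclusive comparisons); exact time ties
  in the bilateral merge order left before right.
* Problem sizes in the test suite — 300–600 s recordings at 100 Hz,
  20-seed replications, a 21-point ROC grid — were chosen so the full
  suite characterises the detector's statistical behaviour in about a
  minute on one core.

## Known limitations

* Validation is synthetic-only; clinical use requires validation against
  an instrumented reference on real recordings.
* The half-stride boundary bias systematically shortens bouts relative to
  insole-style references.
* The single-sensor configuration cannot see contralateral steps: short
  rests inside a bout are tolerated up to 5 s, so closely spaced bouts can
  merge.
* Heel-strike vs. mid-swing event semantics differ between the
  accelerometer and gyroscope paths; the package does not attempt per-peak
  gait-event labelling beyond that.
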