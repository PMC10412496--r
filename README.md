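# gaitbouts

Walking-bout detection from foot-worn inertial sensors.

Continuous monitoring of walking in daily life — how often, how long and
how intensely a person walks — is a key mobility outcome in ageing and
neurological populations, and the first step of every downstream gait
analysis is deciding *when* the wearer was actually walking. `gaitbouts`
implements a robust walking-bout detector for foot-mounted IMUs that works
on the **orientation-invariant norm** of the 3-axis gyroscope (deg/s) or
accelerometer (g) signal, so no sensor-to-segment calibration is needed:

```math
\omega N = \sqrt{\omega_{roll}^2 + \omega_{pitch}^2 + \omega_{yaw}^2}
```

The detection pipeline has three stages:

1. **Peak enhancement** — the norm is downsampled to 40 Hz, linearly
   detrended, low-pass filtered with a zero-phase FIR filter (120
   coefficients, cutoff ≈ 3.2 Hz), transformed with a single-scale
   continuous wavelet transform (second-derivative-of-Gaussian "gaus2"
   kernel, scale 15) and lightly smoothed with a linear Savitzky–Golay
   filter. Each stride collapses into one clean positive peak at the
   mid-swing instant (heel-strike when the accelerometer norm is used).
2. **Peak selection** — stride/step peaks are selected by one of three
   amplitude thresholds: *fixed* (100 deg/s gyro / 0.5 g acc), *adaptive*
   (a percentile, default the 10th, of the peak-amplitude distribution
   above the fixed threshold) or *Hilbert* (a percentile, default the 1st,
   of peak amplitudes inside walking periods pre-selected from the Hilbert
   envelope).
3. **Bout grouping** — successive events whose gap Δtᵢ = tpᵢ₊₁ − tpᵢ stays
   below an adaptive duration threshold belong to one walking bout. For a
   single sensor (stride events) TH_d starts at 5 s and becomes
   `min(3 + mean(stride duration), 5)` s; for two synchronized sensors
   (merged left/right step events) the limits are 3.5 s and
   `min(1.5 + mean(step duration), 3.5)` s. Episodes with fewer than 5
   steps (or 3 same-foot strides) are discarded as non-locomotion.

The package also ships the validation machinery (per-sample confusion
metrics, percentile ROC sweeps) and a synthetic gait-signal simulator with
ground-truth labels, so the full pipeline is testable end to end without
any recorded dataset.

## Worked example

```r
library(gaitbouts)

# simulate 5 minutes of free-living-style data: 3 walking bouts, rest, artifacts
sim <- simulate_recording(sim_config(seed = 42, duration = 300, n_bouts = 3))
sim$recording
#> <imu_recording> unspecified foot, 30000 samples @ 100 Hz (300.0 s), channels: gyro+acc

# detect walking bouts with the adaptive (10th percentile) method
bouts <- detect_walking_bouts(sim$recording, threshold_spec("adaptive"))
for (b in bouts) print(b)
#> <walking_bout> [54.05, 115.60] s, 46 events (single_imu, gyro)
#> <walking_bout> [149.35, 188.95] s, 30 events (single_imu, gyro)
#> <walking_bout> [206.35, 264.95] s, 51 events (single_imu, gyro)

# validate against the simulator's ground truth at the 40 Hz analysis rate
ref  <- truth_labels(sim$truth, duration = 300, fs = 40)
pred <- bouts_to_labels(bouts, duration = 300, fs = 40)
confusion_metrics(pred, ref)
#> <confusion_metrics> TP 6390  TN 5464  FP 0  FN 146
#>   sensitivity 0.978  specificity 1.000  accuracy 0.988  precision 1.000

# how does performance vary with the percentile?
roc_sweep(sim$recording, ref, method = "adaptive", grid = c(1, 10, 25, 50))
#>  percentile       tpr        fpr
#>           1 0.9808752 0.02489019
#>          10 0.9776622 0.00000000
#>          25 0.9019278 0.00000000
#>          50 0.6190330 0.00000000
```

The three detected bouts recover the three simulated ones; the 97.8%
sensitivity / 100% specificity reflect per-sample agreement at 40 Hz, with
the small sensitivity loss coming from the half-stride bias at bout edges
(bout boundaries equal the first/last detected mid-swing peak). The ROC
sweep shows the characteristic trade-off: very low percentiles admit
artifact peaks (non-zero false-positive rate), very high percentiles prune
genuine strides and sensitivity collapses — the 10th percentile is the
sweet spot.

A thin command-line wrapper around the same functions lives at
`inst/cli/gaitbouts.R`:

```sh
Rscript inst/cli/gaitbouts.R simulate --seed 7 --out simdir
Rscript inst/cli/gaitbouts.R detect --input simdir/recording.csv --method adaptive --percentile 10 --out detdir
```

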