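test_that("norm is the elementwise Euclidean length and rejects empties", {
  expect_equal(compute_norm(matrix(c(3, 4, 0), 1)), 5)
  expect_equal(compute_norm(matrix(0, 1, 3)), 0)
  expect_error(compute_norm(matrix(numeric(0), 0, 3)), "empty")
})

test_that("norm is invariant under rotations of the sample frame", {
  set.seed(11)
  m <- matrix(rnorm(20 * 3, sd = 200), ncol = 3)
  base <- compute_norm(m)
  worst <- 0
  for (i in 1:1000) {
    R <- random_rotation()
    worst <- max(worst, max(abs(compute_norm(m %*% t(R)) - base)))
  }
  expect_lt(worst, 1e-9)
})

test_that("downsampling preserves constants, tones and refuses upsampling", {
  const <- rep(100, 1000)
  out <- resample_to_analysis_rate(const, 100, 40)
  expect_length(out, 400)
  expect_lt(max(abs(out - 100)), 1e-6)

  t <- (0:999) / 100
  tone <- sin(2 * pi * 1 * t)
  out <- resample_to_analysis_rate(tone, 100, 40)
  # compare against the analytic tone on the analysis grid, ignoring edges
  t40 <- (seq_along(out) - 1) / 40
  mid <- t40 > 1 & t40 < 9
  expect_lt(max(abs(out[mid] - sin(2 * pi * t40[mid]))), 0.01)

  expect_identical(resample_to_analysis_rate(tone, 100, 100), tone)
  expect_error(resample_to_analysis_rate(tone, 40, 100), "upsampling")
})

test_that("low-pass stage is zero-phase with the designed band edges", {
  n <- 1000
  tri <- pmax(0, 1 - abs((1:n) - 500) / 30)
  out <- zero_phase_lowpass(tri)
  expect_equal(which.max(out), 500)

  t <- (0:2399) / 40
  mid <- 200:2200
  pass <- sin(2 * pi * 0.5 * t)
  got <- zero_phase_lowpass(pass)
  # detrending a pure tone leaves it essentially unchanged; gain within 5%
  expect_gt(max(got[mid]) / max(pass[mid]), 0.95)
  stopb <- sin(2 * pi * 10 * t)
  expect_lt(max(abs(zero_phase_lowpass(stopb)[mid])), 0.05)

  expect_error(zero_phase_lowpass(rnorm(300)), "too short")
})

test_that("wavelet stage matches the direct analytic-kernel correlation", {
  expect_equal(cwt_enhance(rep(0, 500)), rep(0, 500))

  x <- exp(-((1:1000) - 200)^2 / (2 * 5^2))
  y <- cwt_enhance(x)
  expect_lte(abs(which.max(y) - 200), 2)
  idx <- 150:250
  expect_lt(max(abs(y[idx] - direct_gaus2_response(x, 15, idx))), 1e-9)

  t <- (0:799) / 40
  ys <- cwt_enhance(sin(2 * pi * t))
  crests <- which(diff(sign(diff(ys))) == -2) + 1
  crests <- crests[crests > 100 & crests < 700]
  expect_true(all(abs(diff(crests) - 40) <= 1))
})

test_that("wavelet amplitude convention reproduces frozen pywt values", {
  # pywt.cwt(scale 15, 'gaus2') on the same inputs; values computed once
  # with pywavelets 1.9 and frozen here
  t <- seq(0, 100 - 1 / 40, by = 1 / 40)
  bump <- exp(-(t - 50)^2 / (2 * 0.13^2))
  expect_equal(max(cwt_enhance(bump)), 2.5039974834, tolerance = 0.01)
  tone <- sin(2 * pi * t)
  mid <- t > 40 & t < 60
  expect_equal(max(abs(cwt_enhance(tone)[mid])), 4.8855293755,
               tolerance = 0.01)
})

test_that("Savitzky-Golay stage reproduces polynomials and shrinks noise", {
  ramp <- as.numeric(0:99)
  expect_lt(max(abs(savgol_smooth(ramp) - ramp)), 1e-9)
  expect_lt(max(abs(savgol_smooth(rep(3.5, 50)) - 3.5)), 1e-9)
  set.seed(5)
  z <- rnorm(2000)
  expect_lt(var(savgol_smooth(z)), var(z))
  expect_error(savgol_smooth(rnorm(5)), "shorter")
})

test_that("full enhancement recovers the simulated stride peaks", {
  sim <- simulate_recording(sim_config(seed = 1, duration = 60, n_bouts = 1,
                                       strides_per_bout = 10,
                                       artifact_rate = 0))
  sig <- enhance(sim$recording, "gyro")
  peaks <- detect_candidate_peaks(sig)
  n_above <- sum(peaks$amplitudes > 100)
  expect_lte(abs(n_above - 10), 1)
})

test_that("enhancement output is orientation-invariant and tracks length", {
  sim <- simulate_recording(sim_config(seed = 3, duration = 30, n_bouts = 1,
                                       strides_per_bout = 8,
                                       artifact_rate = 0))
  sig <- enhance(sim$recording, "gyro")
  expect_length(sig$values, floor(length(sim$recording$t) * 40 / 100))

  set.seed(99)
  rot <- rotate_recording(sim$recording, random_rotation())
  sig_r <- enhance(rot, "gyro")
  expect_lt(max(abs(sig_r$values - sig$values)),
            1e-6 * max(abs(sig$values)))

  zero <- imu_recording((0:1999) / 100, 100, gyro = matrix(0, 2000, 3))
  expect_equal(enhance(zero, "gyro")$values, rep(0, 800))
  expect_error(enhance(zero, "acc"), "no 'acc' channel")
})

test_that("post-norm chain is linear in the signal amplitude", {
  set.seed(8)
  x <- rnorm(1200, sd = 50)
  chain <- function(v) savgol_smooth(cwt_enhance(zero_phase_lowpass(v)))
  expect_equal(chain(3.7 * x), 3.7 * chain(x), tolerance = 1e-9)
})

test_that("parameter validation catches inconsistent settings", {
  expect_error(enhancement_params(analysis_fs = 6), "twice the FIR cutoff")
  expect_error(enhancement_params(savgol_window = 10), "odd")
  expect_error(enhancement_params(cwt_scale = -1), "positive")
})
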