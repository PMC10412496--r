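#' Configuration for the synthetic gait-signal simulator
#'
#' The simulator emulates what a foot-worn IMU records during free-living
#' monitoring: walking bouts of cyclic strides (a dominant smooth mid-swing
#' angular-velocity bump per stride plus smaller heel-strike/toe-off
#' ripples, and heel-strike impact transients on the accelerometer riding
#' on the 1 g gravity baseline), rest periods of sensor noise, and isolated
#' non-gait movement artifacts. A random fixed mounting rotation is always
#' applied to each simulated sensor, so orientation invariance of the
#' detection chain is exercised on every run.
#'
#' Per-stride mid-swing amplitudes are drawn as a per-bout mean (uniform
#' over `midswing_amp_range`) with ±10% per-stride jitter, mimicking a
#' walker's roughly constant intensity within a bout. Artifact bursts are
#' isolated shakes carrying 1.5–3 Hz oscillation: brisk enough to be
#' non-gait (outside the stride band) yet surviving the 3.2 Hz low-pass,
#' so their enhanced amplitudes straddle the fixed 100 deg/s threshold
#' while staying mostly below the adaptive one — fixed- and
#' adaptive-threshold detections therefore differ measurably.
#'
#' @param seed integer RNG seed; the simulation is fully deterministic
#'   given the seed.
#' @param duration total recording duration in s.
#' @param fs sampling rate in Hz (>= 40).
#' @param n_bouts number of walking bouts (0 allowed).
#' @param stride_duration_range per-bout mean stride duration range in s
#'   (slow-walker presets go up to 3.0).
#' @param midswing_amp_range mid-swing angular-velocity bump amplitude
#'   range in deg/s.
#' @param rest_noise_std gyroscope white-noise standard deviation in deg/s.
#' @param artifact_rate non-gait artifact events per minute.
#' @param artifact_amp_range artifact amplitude range in deg/s.
#' @param bilateral if TRUE, simulate synchronized left/right sensors with
#'   left strides offset by half a stride.
#' @param asymmetry_ratio left/right mid-swing amplitude ratio.
#' @param strides_per_bout optional exact stride count per bout (scalar or
#'   length `n_bouts`); when NULL, bout lengths derive from
#'   `walk_fraction`.
#' @param walk_fraction fraction of the recording spent walking when
#'   `strides_per_bout` is NULL.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1, duration = 600, fs = 100, n_bouts = 3,
                       stride_duration_range = c(0.9, 1.4),
                       midswing_amp_range = c(250, 500),
                       rest_noise_std = 5, artifact_rate = 2,
                       artifact_amp_range = c(80, 250),
                       bilateral = FALSE, asymmetry_ratio = 1,
                       strides_per_bout = NULL, walk_fraction = 0.55) {
  ordered2 <- function(r) length(r) == 2L && r[1] <= r[2] && all(r > 0)
  if (!ordered2(stride_duration_range)) stop("bad 'stride_duration_range'")
  if (!ordered2(midswing_amp_range)) stop("bad 'midswing_amp_range'")
  if (!ordered2(artifact_amp_range)) stop("bad 'artifact_amp_range'")
  if (fs < 40) stop("'fs' must be at least 40 Hz")
  if (n_bouts < 0) stop("'n_bouts' must be non-negative")
  if (!is.null(strides_per_bout)) {
    strides_per_bout <- rep_len(as.integer(strides_per_bout), max(n_bouts, 1L))
    if (n_bouts > 0 && any(strides_per_bout < 5L)) {
      stop("'strides_per_bout' must be at least 5")
    }
  }
  if (walk_fraction <= 0 || walk_fraction >= 1) {
    stop("'walk_fraction' must be in (0, 1)")
  }
  # rough feasibility: bouts of at least five strides plus rest margins
  if (n_bouts > 0) {
    need <- n_bouts * 5 * stride_duration_range[1] + 8 * (n_bouts + 1)
    if (duration < need) {
      stop("'duration' too short for ", n_bouts, " bouts plus rests")
    }
  }
  structure(list(seed = as.integer(seed), duration = duration, fs = fs,
                 n_bouts = as.integer(n_bouts),
                 stride_duration_range = stride_duration_range,
                 midswing_amp_range = midswing_amp_range,
                 rest_noise_std = rest_noise_std,
                 artifact_rate = artifact_rate,
                 artifact_amp_range = artifact_amp_range,
                 bilateral = isTRUE(bilateral),
                 asymmetry_ratio = asymmetry_ratio,
                 strides_per_bout = strides_per_bout,
                 walk_fraction = walk_fraction),
            class = "sim_config")
}

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Draw a uniformly random 3D rotation matrix
#'
#' QR-based Haar sample with the determinant fixed to +1; used as the fixed
#' sensor-mounting rotation in the simulator and for orientation-invariance
#' testing.
#'
#' @return 3 x 3 rotation matrix.
#' @export
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3L))
  q <- qr.Q(qr_)
  d <- sign(diag(qr.R(qr_)))
  q <- q %*% diag(d)
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

#' Apply a fixed rotation to every sample of a recording
#'
#' Rotates the gyroscope and accelerometer 3-vectors by `R`, emulating a
#' different sensor-mounting orientation. Detection built on signal norms
#' is invariant to this.
#'
#' @param recording an [imu_recording()].
#' @param R 3 x 3 rotation matrix.
#' @return the rotated [imu_recording()].
#' @export
rotate_recording <- function(recording, R) {
  stopifnot(inherits(recording, "imu_recording"))
  rot <- function(m) if (is.null(m)) NULL else m %*% t(R)
  imu_recording(recording$t, recording$fs, gyro = rot(recording$gyro),
                acc = rot(recording$acc), side = recording$side)
}

gauss_bump <- function(t, center, sigma, amp) {
  amp * exp(-(t - center)^2 / (2 * sigma^2))
}

# one foot's raw channels from a stride schedule + artifact schedule
synth_foot <- function(t, strides, artifacts, noise_sd) {
  n <- length(t)
  gyro <- matrix(stats::rnorm(3L * n, sd = noise_sd), ncol = 3L)
  acc <- matrix(stats::rnorm(3L * n, sd = 0.02), ncol = 3L)
  acc[, 3L] <- acc[, 3L] + 1 # gravity baseline
  if (nrow(strides)) {
    for (i in seq_len(nrow(strides))) {
      s <- strides[i, ]
      # dominant mid-swing bump on the pitch axis
      gyro[, 2L] <- gyro[, 2L] + gauss_bump(t, s$center, 0.11 * s$dur, s$amp)
      # smaller heel-strike / toe-off ripples on the other axes
      hs <- s$center + 0.35 * s$dur
      to <- s$center - 0.35 * s$dur
      gyro[, 1L] <- gyro[, 1L] + gauss_bump(t, hs, 0.05 * s$dur, 0.25 * s$amp)
      gyro[, 3L] <- gyro[, 3L] + gauss_bump(t, to, 0.05 * s$dur, 0.20 * s$amp)
      # heel-strike loading on the accelerometer: broad impact bump plus a
      # sharp transient, both well above 0.8 g
      acc[, 3L] <- acc[, 3L] + gauss_bump(t, hs, 0.15 * s$dur, s$acc_amp) +
        gauss_bump(t, hs, 0.02, s$acc_spike)
    }
  }
  if (nrow(artifacts)) {
    for (i in seq_len(nrow(artifacts))) {
      a <- artifacts[i, ]
      w <- numeric(n)
      inwin <- abs(t - a$center) < a$dur / 2
      w[inwin] <- 0.5 * (1 + cos(2 * pi * (t[inwin] - a$center) / a$dur))
      osc <- w * sin(2 * pi * a$freq * (t - a$center) + a$phase)
      gyro[, 2L] <- gyro[, 2L] + a$amp * osc
      gyro[, 1L] <- gyro[, 1L] + 0.5 * a$amp * osc
      acc[, 3L] <- acc[, 3L] + a$amp / 300 * osc
    }
  }
  list(gyro = gyro, acc = acc)
}

#' Simulate a foot-worn IMU recording with ground truth
#'
#' Lays out `n_bouts` walking bouts separated by rest periods of at least
#' 8 s, draws per-bout cadence and amplitude, synthesises the raw 3-axis
#' gyroscope and accelerometer channels, applies a random fixed mounting
#' rotation per sensor, and returns the recording(s) together with
#' per-sample ground-truth labels and the bout/stride schedule.
#'
#' @param config a [sim_config()].
#' @return list with elements `recording` (an [imu_recording()], or
#'   `list(left=, right=)` when bilateral), `truth` (list with `labels`, a
#'   [label_vector()] at the raw rate, and `bouts`, a list of per-bout
#'   schedules with stride times per foot), and `config`.
#' @export
simulate_recording <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    B <- config$n_bouts
    fs <- config$fs
    t <- seq(0, config$duration - 1 / fs, by = 1 / fs)
    stride_sets <- list()
    bout_len <- numeric(B)
    if (B > 0) {
      m_b <- stats::runif(B, config$stride_duration_range[1],
                          config$stride_duration_range[2])
      a_b <- stats::runif(B, config$midswing_amp_range[1],
                          config$midswing_amp_range[2])
      if (!is.null(config$strides_per_bout)) {
        counts <- config$strides_per_bout
      } else {
        w <- stats::runif(B, 0.5, 1)
        L_b <- config$walk_fraction * config$duration * w / sum(w)
        counts <- pmax(5L, as.integer(floor(L_b / m_b)))
      }
      for (b in seq_len(B)) {
        d <- m_b[b] * stats::runif(counts[b], 0.95, 1.05)
        amp <- a_b[b] * stats::runif(counts[b], 0.9, 1.1)
        stride_sets[[b]] <- data.frame(
          dur = d, amp = amp,
          center = cumsum(d) - d / 2, # relative to bout start
          acc_amp = stats::runif(counts[b], 1.5, 2.5),
          acc_spike = stats::runif(counts[b], 1.5, 3))
        bout_len[b] <- sum(d) + if (config$bilateral) d[counts[b]] / 2 else 0
      }
    }
    total_rest <- config$duration - sum(bout_len)
    min_rest <- 8
    if (total_rest < min_rest * (B + 1)) {
      stop("infeasible config: bouts plus minimum rests exceed the duration")
    }
    z <- stats::runif(B + 1)
    rests <- min_rest + (total_rest - min_rest * (B + 1)) * z / sum(z)
    bout_start <- if (B > 0) {
      cumsum(c(rests[1], if (B > 1) bout_len[1:(B - 1)] + rests[2:B]))
    } else {
      numeric(0)
    }

    gt_bouts <- list()
    all_strides_r <- all_strides_l <- list()
    for (b in seq_len(B)) {
      s <- stride_sets[[b]]
      r_times <- bout_start[b] + s$center
      l_times <- r_times + s$dur / 2
      gt_bouts[[b]] <- list(
        start = bout_start[b],
        end = bout_start[b] + bout_len[b],
        stride_times_right = r_times,
        stride_times_left = if (config$bilateral) l_times else numeric(0))
      sr <- s
      sr$center <- r_times
      all_strides_r[[b]] <- sr
      sl <- s
      sl$center <- l_times
      sl$amp <- sl$amp * config$asymmetry_ratio
      all_strides_l[[b]] <- sl
    }
    empty_strides <- data.frame(dur = numeric(0), amp = numeric(0),
                                center = numeric(0), acc_amp = numeric(0),
                                acc_spike = numeric(0))
    strides_r <- if (B > 0) do.call(rbind, all_strides_r) else empty_strides
    strides_l <- if (B > 0) do.call(rbind, all_strides_l) else empty_strides

    draw_artifacts <- function() {
      n_art <- stats::rpois(1L, config$artifact_rate * config$duration / 60)
      out <- data.frame(center = numeric(0), dur = numeric(0),
                        freq = numeric(0), amp = numeric(0),
                        phase = numeric(0))
      if (n_art == 0L) return(out)
      # rest windows with a safety margin around bout edges
      seg_start <- c(0, vapply(gt_bouts, `[[`, numeric(1), "end"))
      seg_end <- c(if (B > 0) vapply(gt_bouts, `[[`, numeric(1), "start"),
                   config$duration)
      for (k in seq_len(n_art)) {
        dur <- stats::runif(1, 0.5, 2)
        lo <- seg_start + 2.5 + dur / 2
        hi <- seg_end - 2.5 - dur / 2
        ok <- which(hi > lo)
        if (length(ok) == 0L) next
        seg <- ok[sample.int(length(ok), 1L,
                             prob = (hi - lo)[ok])]
        center <- stats::runif(1, lo[seg], hi[seg])
        # shakes are isolated events: drop draws overlapping an accepted one
        if (any(abs(out$center - center) < 3)) next
        out <- rbind(out, data.frame(
          center = center, dur = dur,
          freq = stats::runif(1, 1.5, 3),
          amp = stats::runif(1, config$artifact_amp_range[1],
                             config$artifact_amp_range[2]),
          phase = stats::runif(1, 0, 2 * pi)))
      }
      out
    }

    build <- function(strides, side) {
      arts <- draw_artifacts()
      chans <- synth_foot(t, strides, arts, config$rest_noise_std)
      R <- random_rotation()
      imu_recording(t, fs, gyro = chans$gyro %*% t(R),
                    acc = chans$acc %*% t(R), side = side)
    }

    recording <- if (config$bilateral) {
      list(left = build(strides_l, "left"), right = build(strides_r, "right"))
    } else {
      build(strides_r, "unspecified")
    }

    lab <- rep(0L, length(t))
    for (b in gt_bouts) lab[t >= b$start & t < b$end] <- 1L
    truth <- list(labels = label_vector(lab, fs), bouts = gt_bouts)
    list(recording = recording, truth = truth, config = config)
  })
}

#' Reference labels on the analysis clock
#'
#' Resamples the simulator's ground-truth bout schedule to a label vector
#' at the stated rate (the 40 Hz analysis rate by default), for comparison
#' with detector output.
#'
#' @param truth the `truth` element returned by [simulate_recording()].
#' @param duration recording duration in s.
#' @param fs label rate in Hz.
#' @return a [label_vector()].
#' @export
truth_labels <- function(truth, duration, fs = 40) {
  n <- round(duration * fs)
  tk <- (seq_len(n) - 1L) / fs
  lab <- rep(0L, n)
  for (b in truth$bouts) lab[tk >= b$start & tk < b$end] <- 1L
  label_vector(lab, fs)
}

#' Ready-made small simulation scenarios
#'
#' Short (at most 60 s) scenarios with documented expected detector
#' behaviour, used as programmatic test fixtures:
#' \describe{
#'   \item{clean_walk}{one bout of 10 strides, no artifacts.}
#'   \item{slow_walk}{one bout of 8 slow strides (2.5–3.0 s).}
#'   \item{artifact_storm}{two bouts of 10 strides each, plus a
#'     deterministic train of three non-gait shakes in the longest rest
#'     period, spaced so the fixed threshold chains them into a spurious
#'     bout while the adaptive threshold prunes them.}
#'   \item{asymmetric_dual}{bilateral recording, left amplitudes at 70%.}
#'   \item{rest_only}{no locomotion at all.}
#' }
#'
#' @param name scenario name.
#' @return as [simulate_recording()].
#' @export
make_toy_fixture <- function(name = c("clean_walk", "slow_walk",
                                      "artifact_storm", "asymmetric_dual",
                                      "rest_only")) {
  name <- match.arg(name)
  cfg <- switch(name,
    clean_walk = sim_config(seed = 101, duration = 40, n_bouts = 1,
                            strides_per_bout = 10, artifact_rate = 0),
    slow_walk = sim_config(seed = 102, duration = 60, n_bouts = 1,
                           strides_per_bout = 8,
                           stride_duration_range = c(2.5, 3.0),
                           midswing_amp_range = c(250, 400),
                           artifact_rate = 0),
    artifact_storm = sim_config(seed = 103, duration = 60, n_bouts = 2,
                                strides_per_bout = 10, artifact_rate = 0),
    asymmetric_dual = sim_config(seed = 104, duration = 45, n_bouts = 1,
                                 strides_per_bout = 12, bilateral = TRUE,
                                 asymmetry_ratio = 0.7, artifact_rate = 0),
    rest_only = sim_config(seed = 105, duration = 30, n_bouts = 0,
                           artifact_rate = 0))
  sim <- simulate_recording(cfg)
  if (name == "artifact_storm") sim <- add_shake_train(sim)
  sim
}

# artifact_storm carries a deterministic non-gait burst train: three 1.5 Hz
# shakes of 200 deg/s, 3.5 s apart, in the longest rest period. Their
# spacing sits under the 5 s single-sensor gap limit (so the fixed method
# chains them into a spurious bout) and their enhanced amplitude lies
# between the fixed threshold and the weakest stride peak (so the adaptive
# percentile threshold prunes them) - the false-positive contrast between
# the two methods is therefore present by construction, not by chance.
add_shake_train <- function(sim) {
  rec <- sim$recording
  bs <- vapply(sim$truth$bouts, `[[`, numeric(1), "start")
  be <- vapply(sim$truth$bouts, `[[`, numeric(1), "end")
  rest_start <- c(0, be)
  rest_end <- c(bs, sim$config$duration)
  k <- which.max(rest_end - rest_start)
  centers <- rest_start[k] + 2.5 + 3.5 * (0:2)
  stopifnot(max(centers) + 1.5 < rest_end[k])
  g <- rec$gyro
  for (c0 in centers) {
    w <- numeric(length(rec$t))
    inwin <- abs(rec$t - c0) < 1
    w[inwin] <- 0.5 * (1 + cos(pi * (rec$t[inwin] - c0)))
    g[, 2L] <- g[, 2L] + 200 * w * sin(2 * pi * 1.5 * (rec$t - c0))
  }
  sim$recording <- imu_recording(rec$t, rec$fs, gyro = g, acc = rec$acc,
                                 side = rec$side)
  sim$shake_times <- centers
  sim
}
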