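#' Bout-grouping parameters
#'
#' Consecutive selected peaks are grouped into a walking bout while the gap
#' between them stays at or below an adaptive duration threshold. The
#' threshold starts at `init_gap` and, once the current bout holds at least
#' two events, becomes `update_offset` plus the mean intra-bout inter-event
#' duration, capped at `gap_cap` — so it tracks the walker's cadence while
#' still tolerating short breaks or an occasional missed peak. The defaults
#' accommodate slow walking down to about 40 steps/min (3 s strides).
#'
#' Single-sensor events are same-foot strides (gap limit 5 s, offset 3 s);
#' dual-sensor events are merged left/right steps (gap limit 3.5 s, offset
#' 1.5 s). After grouping, only bouts with at least `min_events` events
#' count as true locomotion: 5 steps in the dual configuration, or 3
#' same-foot strides in the single configuration (the smallest stride count
#' implying at least five steps).
#'
#' @param config sensor configuration.
#' @param init_gap initial inter-event gap limit in s, also the cap.
#' @param update_offset seconds added to the mean intra-bout event-to-event
#'   duration when updating the gap limit.
#' @param gap_cap upper bound on the adaptive gap limit in s.
#' @param min_events minimum event count for a retained bout.
#' @return an object of class `grouping_params`.
#' @export
grouping_params <- function(config = c("single_imu", "dual_imu"),
                            init_gap = NULL, update_offset = NULL,
                            gap_cap = NULL, min_events = NULL) {
  config <- match.arg(config)
  defaults <- if (config == "single_imu") {
    list(init_gap = 5, update_offset = 3, gap_cap = 5, min_events = 3L)
  } else {
    list(init_gap = 3.5, update_offset = 1.5, gap_cap = 3.5, min_events = 5L)
  }
  if (is.null(init_gap)) init_gap <- defaults$init_gap
  if (is.null(update_offset)) update_offset <- defaults$update_offset
  if (is.null(gap_cap)) gap_cap <- init_gap
  if (is.null(min_events)) min_events <- defaults$min_events
  if (init_gap <= 0) stop("'init_gap' must be positive")
  if (update_offset < 0) stop("'update_offset' must be non-negative")
  if (min_events < 1) stop("'min_events' must be at least 1")
  structure(list(config = config, init_gap = init_gap,
                 update_offset = update_offset, gap_cap = gap_cap,
                 min_events = as.integer(min_events)),
            class = "grouping_params")
}

#' Group event times into walking bouts with the adaptive gap limit
#'
#' Left-to-right scan over the sorted event times. The current bout's gap
#' limit is `init_gap` until the bout holds two events, then
#' `min(update_offset + mean(intra-bout inter-event durations), gap_cap)`,
#' recomputed after every accepted event. A gap at or below the limit
#' extends the bout; a larger gap closes it and starts a new one. Bout
#' start/end equal the first/last member event time. No minimum-size filter
#' is applied here — see [filter_true_locomotion()].
#'
#' @param peak_times strictly increasing event times in seconds.
#' @param params a [grouping_params()].
#' @param source signal source recorded on the returned bouts.
#' @return list of [walking_bout()] objects partitioning `peak_times`.
#' @export
group_events <- function(peak_times, params = grouping_params(),
                         source = c("gyro", "acc")) {
  source <- match.arg(source)
  peak_times <- as.numeric(peak_times)
  if (length(peak_times) == 0L) return(list())
  if (any(diff(peak_times) < 0)) {
    stop("'peak_times' must be sorted")
  }
  bouts <- list()
  cur <- peak_times[1L]
  for (i in seq_along(peak_times)[-1L]) {
    gap <- peak_times[i] - peak_times[i - 1L]
    th_d <- if (length(cur) >= 2L) {
      min(params$update_offset + mean(diff(cur)), params$gap_cap)
    } else {
      params$init_gap
    }
    if (gap <= th_d) {
      cur <- c(cur, peak_times[i])
    } else {
      bouts[[length(bouts) + 1L]] <-
        walking_bout(cur, config = params$config, source = source)
      cur <- peak_times[i]
    }
  }
  bouts[[length(bouts) + 1L]] <-
    walking_bout(cur, config = params$config, source = source)
  bouts
}

#' Merge left- and right-foot peak sets into step events
#'
#' The two feet's selected mid-swing peaks, on the same synchronized clock,
#' interleave into one sorted step-event sequence. Exact ties are broken
#' left before right so the merge is deterministic.
#'
#' @param left,right [peak_set()] objects from the left and right sensors.
#' @return sorted numeric vector of `length(left) + length(right)` step
#'   event times.
#' @export
merge_bilateral <- function(left, right) {
  stopifnot(inherits(left, "peak_set"), inherits(right, "peak_set"))
  times <- c(left$times, right$times)
  side <- rep(c(0L, 1L), c(length(left$times), length(right$times)))
  times[order(times, side)]
}

#' Keep only bouts that qualify as true locomotion
#'
#' Episodes with fewer than `min_events` member events (5 merged steps in
#' the dual configuration, 3 same-foot strides in the single configuration)
#' are discarded as non-locomotion.
#'
#' @param bouts list of [walking_bout()] objects.
#' @param params a [grouping_params()].
#' @return filtered list of bouts.
#' @export
filter_true_locomotion <- function(bouts, params = grouping_params()) {
  Filter(function(b) length(b$events) >= params$min_events, bouts)
}

#' Detect walking bouts from one or two foot-worn recordings
#'
#' Full pipeline: peak enhancement of the chosen signal norm, candidate peak
#' detection, amplitude thresholding per foot, merging of left/right events
#' in the dual configuration, adaptive-gap grouping and the true-locomotion
#' filter. In the dual configuration the amplitude thresholds are computed
#' per foot independently (they may differ slightly for asymmetric gait) and
#' the merged events are then treated uniformly.
#'
#' @param recordings a single [imu_recording()] (single-sensor
#'   configuration) or a list with elements `left` and `right`
#'   (dual-sensor configuration, synchronized clocks).
#' @param spec a [threshold_spec()].
#' @param eparams an [enhancement_params()].
#' @param gparams a [grouping_params()]; defaults to the configuration
#'   implied by `recordings`.
#' @param source which channel to use, `"gyro"` or `"acc"`.
#' @return list of [walking_bout()] objects, time-ordered and
#'   non-overlapping.
#' @export
detect_walking_bouts <- function(recordings, spec = threshold_spec("adaptive"),
                                 eparams = enhancement_params(),
                                 gparams = NULL,
                                 source = c("gyro", "acc")) {
  source <- match.arg(source)
  dual <- !inherits(recordings, "imu_recording")
  if (dual) {
    if (!is.list(recordings) || !all(c("left", "right") %in% names(recordings))) {
      stop("'recordings' must be an imu_recording or list(left=, right=)")
    }
    left <- recordings$left
    right <- recordings$right
    stopifnot(inherits(left, "imu_recording"), inherits(right, "imu_recording"))
    if (abs(left$t[1L] - right$t[1L]) > 1 / min(left$fs, right$fs)) {
      stop("left/right recordings are not synchronized (start-time mismatch)")
    }
    if (is.null(gparams)) gparams <- grouping_params("dual_imu")
    sel <- lapply(list(left, right), function(rec) {
      sig <- enhance(rec, source = source, params = eparams)
      select_peaks(detect_candidate_peaks(sig), sig, spec)
    })
    events <- merge_bilateral(sel[[1L]], sel[[2L]])
  } else {
    if (is.null(gparams)) gparams <- grouping_params("single_imu")
    sig <- enhance(recordings, source = source, params = eparams)
    sel <- select_peaks(detect_candidate_peaks(sig), sig, spec)
    events <- sel$times
  }
  if (length(events) == 0L) return(list())
  filter_true_locomotion(group_events(events, gparams, source = source),
                         gparams)
}
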