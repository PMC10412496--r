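#' Amplitude-threshold specification for peak selection
#'
#' Three methods select stride/step peaks from the enhanced signal:
#' \describe{
#'   \item{fixed}{keep peaks at or above a conservative fixed amplitude
#'     (100 deg/s for the gyroscope norm, 0.5 g for the accelerometer norm),
#'     chosen low so slow walkers are not missed.}
#'   \item{adaptive}{apply the fixed threshold first, then keep peaks at or
#'     above a percentile (default 10) of the surviving amplitude
#'     distribution — a subject-specific threshold requiring no a-priori
#'     value.}
#'   \item{hilbert}{pre-select candidate walking periods where the Hilbert
#'     envelope of the enhanced signal stays above the fixed threshold, then
#'     keep in-period peaks at or above a percentile (default 1) of the
#'     in-period amplitude distribution.}
#' }
#' All comparisons are inclusive (`>=`) so tie behaviour is deterministic.
#'
#' @param method thresholding method.
#' @param percentile percentile in (0, 50] for the adaptive/hilbert methods;
#'   defaults to 10 (adaptive) or 1 (hilbert).
#' @param fixed_gyro fixed threshold for the gyroscope norm, deg/s.
#' @param fixed_acc fixed threshold for the acceleration norm, g.
#' @param hilbert_min_dur minimum duration (s) the envelope must stay above
#'   the fixed threshold for a pre-selected period to be kept.
#' @param hilbert_gap_merge sub-threshold gaps shorter than this (s) are
#'   merged into the surrounding pre-selected period.
#' @return an object of class `threshold_spec`.
#' @export
threshold_spec <- function(method = c("fixed", "adaptive", "hilbert"),
                           percentile = NULL, fixed_gyro = 100,
                           fixed_acc = 0.5, hilbert_min_dur = 1,
                           hilbert_gap_merge = 3) {
  method <- match.arg(method)
  if (is.null(percentile)) {
    percentile <- switch(method, adaptive = 10, hilbert = 1, NA_real_)
  }
  if (method != "fixed") {
    if (!is.finite(percentile) || percentile <= 0 || percentile > 50) {
      stop("'percentile' must be in (0, 50]")
    }
  }
  if (fixed_gyro <= 0 || fixed_acc <= 0) stop("fixed thresholds must be > 0")
  structure(list(method = method, percentile = percentile,
                 fixed_gyro = fixed_gyro, fixed_acc = fixed_acc,
                 hilbert_min_dur = hilbert_min_dur,
                 hilbert_gap_merge = hilbert_gap_merge),
            class = "threshold_spec")
}

fixed_threshold_for <- function(spec, source) {
  switch(source, gyro = spec$fixed_gyro, acc = spec$fixed_acc,
         stop("unknown source '", source, "'"))
}

#' Construct a peak set
#'
#' @param times peak times in seconds on the analysis clock, strictly
#'   increasing.
#' @param amplitudes peak amplitudes, same length and units as the enhanced
#'   signal.
#' @param method how the set was produced.
#' @param threshold_value amplitude threshold actually applied (`-Inf` for
#'   raw candidates).
#' @param source signal source the peaks come from.
#' @return an object of class `peak_set`.
#' @export
peak_set <- function(times, amplitudes,
                     method = c("candidates", "fixed", "adaptive", "hilbert"),
                     threshold_value = -Inf, source = c("gyro", "acc")) {
  method <- match.arg(method)
  source <- match.arg(source)
  times <- as.numeric(times)
  amplitudes <- as.numeric(amplitudes)
  if (length(times) != length(amplitudes)) {
    stop("'times' and 'amplitudes' must have the same length")
  }
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("peak times must be strictly increasing")
  }
  structure(list(times = times, amplitudes = amplitudes, method = method,
                 threshold_value = threshold_value, source = source),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> %d peaks (%s, %s), threshold %s\n",
              length(x$times), x$method, x$source,
              if (is.finite(x$threshold_value))
                sprintf("%.3g", x$threshold_value) else "none"))
  invisible(x)
}

subset_peaks <- function(ps, keep, method, threshold_value) {
  peak_set(ps$times[keep], ps$amplitudes[keep], method = method,
           threshold_value = threshold_value, source = ps$source)
}

#' Detect all candidate peaks on an enhanced signal
#'
#' Candidates are strict local maxima (greater than both neighbours);
#' a plateau of equal values flanked by lower values counts once, at its
#' centre sample. No minimum-distance constraint is applied — the
#' enhancement chain already band-limits the signal near stride frequency.
#'
#' @param signal an `enhanced_signal`.
#' @return a [peak_set()] with `method = "candidates"`.
#' @export
detect_candidate_peaks <- function(signal) {
  stopifnot(inherits(signal, "enhanced_signal"))
  v <- signal$values
  if (length(v) < 3L) {
    return(peak_set(numeric(0), numeric(0), method = "candidates",
                    source = signal$source))
  }
  r <- rle(v)
  nr <- length(r$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- integer(0)
  if (nr >= 3L) {
    for (i in 2L:(nr - 1L)) {
      if (r$values[i] > r$values[i - 1L] && r$values[i] > r$values[i + 1L]) {
        idx <- c(idx, (starts[i] + ends[i]) %/% 2L)
      }
    }
  }
  peak_set((idx - 1L) / signal$fs, v[idx], method = "candidates",
           source = signal$source)
}

#' Select peaks with the fixed amplitude threshold
#'
#' @param candidates a [peak_set()] of candidate peaks.
#' @param spec a [threshold_spec()].
#' @return a [peak_set()] of peaks with amplitude at or above the source's
#'   fixed threshold.
#' @export
select_fixed <- function(candidates, spec = threshold_spec("fixed")) {
  stopifnot(inherits(candidates, "peak_set"))
  th <- fixed_threshold_for(spec, candidates$source)
  subset_peaks(candidates, candidates$amplitudes >= th, "fixed", th)
}

#' Select peaks with the adaptive percentile threshold
#'
#' Applies the fixed threshold, computes the stated percentile of the
#' surviving amplitude distribution (linear interpolation between closest
#' ranks) and keeps peaks at or above it. The adaptive threshold can never
#' fall below the fixed one.
#'
#' @inheritParams select_fixed
#' @return a [peak_set()]; if no peak survives the fixed threshold, an empty
#'   set whose `threshold_value` is the fixed threshold.
#' @export
select_adaptive <- function(candidates, spec = threshold_spec("adaptive")) {
  s1 <- select_fixed(candidates, spec)
  if (length(s1$times) == 0L) {
    return(subset_peaks(s1, logical(0), "adaptive", s1$threshold_value))
  }
  th <- unname(stats::quantile(s1$amplitudes, spec$percentile / 100,
                               type = 7))
  subset_peaks(s1, s1$amplitudes >= th, "adaptive", th)
}

# analytic-signal magnitude via FFT (one-sided spectrum doubling)
hilbert_envelope <- function(x) {
  n <- length(x)
  if (n == 0L) stop("empty input")
  h <- rep(0, n)
  h[1L] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1L] <- 1
    if (n > 2) h[2:(n / 2)] <- 2
  } else if (n > 1) {
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(stats::fft(x) * h, inverse = TRUE) / n)
}

#' Pre-select candidate walking periods from the Hilbert envelope
#'
#' The Hilbert (analytic-signal) envelope of the enhanced signal is a smooth
#' amplitude trace; periods where it stays at or above the source's fixed
#' threshold, after merging gaps shorter than `hilbert_gap_merge` and
#' dropping periods shorter than `hilbert_min_dur`, are returned as
#' candidate walking periods.
#'
#' @param signal an `enhanced_signal`.
#' @param spec a [threshold_spec()].
#' @return data frame with columns `start`, `end` (seconds, half-open
#'   intervals); zero rows when nothing qualifies.
#' @export
hilbert_preselect <- function(signal, spec = threshold_spec("hilbert")) {
  stopifnot(inherits(signal, "enhanced_signal"))
  env <- hilbert_envelope(signal$values)
  th <- fixed_threshold_for(spec, signal$source)
  above <- env >= th
  if (!any(above)) return(data.frame(start = numeric(0), end = numeric(0)))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  per <- data.frame(start = (starts[r$values] - 1L) / signal$fs,
                    end = ends[r$values] / signal$fs)
  # merge short gaps
  if (nrow(per) > 1L) {
    keep_start <- per$start[1L]
    merged <- list()
    cur_end <- per$end[1L]
    for (i in 2L:nrow(per)) {
      if (per$start[i] - cur_end < spec$hilbert_gap_merge) {
        cur_end <- per$end[i]
      } else {
        merged[[length(merged) + 1L]] <- c(keep_start, cur_end)
        keep_start <- per$start[i]
        cur_end <- per$end[i]
      }
    }
    merged[[length(merged) + 1L]] <- c(keep_start, cur_end)
    m <- do.call(rbind, merged)
    per <- data.frame(start = m[, 1L], end = m[, 2L])
  }
  per[per$end - per$start >= spec$hilbert_min_dur, , drop = FALSE]
}

#' Select peaks with the Hilbert-envelope method
#'
#' Restricts candidates to the pre-selected walking periods, computes the
#' stated percentile (default 1) of the in-period amplitude distribution and
#' keeps in-period peaks at or above it.
#'
#' @param candidates a [peak_set()] of candidate peaks.
#' @param signal the `enhanced_signal` the candidates were detected on.
#' @param spec a [threshold_spec()].
#' @return a [peak_set()]; empty when the pre-selection is empty.
#' @export
select_hilbert <- function(candidates, signal,
                           spec = threshold_spec("hilbert")) {
  stopifnot(inherits(candidates, "peak_set"))
  per <- hilbert_preselect(signal, spec)
  if (nrow(per) == 0L || length(candidates$times) == 0L) {
    return(subset_peaks(candidates, logical(0), "hilbert", NA_real_))
  }
  inside <- vapply(candidates$times, function(tp) {
    any(per$start <= tp & tp < per$end)
  }, logical(1))
  if (!any(inside)) {
    return(subset_peaks(candidates, logical(0), "hilbert", NA_real_))
  }
  th <- unname(stats::quantile(candidates$amplitudes[inside],
                               spec$percentile / 100, type = 7))
  subset_peaks(candidates, inside & candidates$amplitudes >= th,
               "hilbert", th)
}

#' Select peaks by the method named in a threshold specification
#'
#' Dispatch helper used by the full pipeline.
#'
#' @inheritParams select_hilbert
#' @return a [peak_set()].
#' @export
select_peaks <- function(candidates, signal, spec) {
  switch(spec$method,
         fixed = select_fixed(candidates, spec),
         adaptive = select_adaptive(candidates, spec),
         hilbert = select_hilbert(candidates, signal, spec))
}
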