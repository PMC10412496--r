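#' Convert walking bouts to a per-sample binary label vector
#'
#' Sample k (time k/fs, k = 0, 1, ...) is labelled 1 exactly when it falls
#' inside some bout interval, taken half-open `[start, end)` so adjacent
#' bouts tile without double counting.
#'
#' @param bouts list of [walking_bout()] objects, all within
#'   `[0, duration]`.
#' @param duration recording duration in seconds.
#' @param fs label rate in Hz (the analysis rate, 40 Hz, by default).
#' @return a [label_vector()] of `round(duration * fs)` samples.
#' @export
bouts_to_labels <- function(bouts, duration, fs = 40) {
  n <- round(duration * fs)
  if (n < 1L) stop("'duration' too short for the label rate")
  tk <- (seq_len(n) - 1L) / fs
  lab <- rep(0L, n)
  for (b in bouts) {
    stopifnot(inherits(b, "walking_bout"))
    if (b$start < -1e-9 || b$end > duration + 1e-9) {
      stop("bout [", b$start, ", ", b$end, "] outside recording duration ",
           duration)
    }
    lab[tk >= b$start & tk < b$end] <- 1L
  }
  label_vector(lab, fs = fs)
}

#' Per-sample confusion metrics between predicted and reference labels
#'
#' Counts true/false positives/negatives by elementwise comparison and
#' derives sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), accuracy =
#' (TP+TN)/total and precision = TP/(TP+FP). A rate whose denominator is
#' zero (a class absent from the comparison) is reported as `NaN`, never 0.
#'
#' @param pred predicted [label_vector()].
#' @param ref reference [label_vector()], same length and rate.
#' @return an object of class `confusion_metrics`.
#' @export
confusion_metrics <- function(pred, ref) {
  stopifnot(inherits(pred, "label_vector"), inherits(ref, "label_vector"))
  if (length(pred$values) != length(ref$values)) {
    stop("prediction and reference have different lengths")
  }
  if (pred$fs != ref$fs) stop("prediction and reference rates differ")
  p <- pred$values
  r <- ref$values
  tp <- sum(p == 1L & r == 1L)
  tn <- sum(p == 0L & r == 0L)
  fp <- sum(p == 1L & r == 0L)
  fn <- sum(p == 0L & r == 1L)
  rate <- function(num, den) if (den == 0L) NaN else num / den
  structure(list(TP = tp, TN = tn, FP = fp, FN = fn,
                 sensitivity = rate(tp, tp + fn),
                 specificity = rate(tn, tn + fp),
                 accuracy = rate(tp + tn, tp + tn + fp + fn),
                 precision = rate(tp, tp + fp)),
            class = "confusion_metrics")
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf("<confusion_metrics> TP %d  TN %d  FP %d  FN %d\n",
              x$TP, x$TN, x$FP, x$FN))
  cat(sprintf("  sensitivity %.3f  specificity %.3f  accuracy %.3f  precision %.3f\n",
              x$sensitivity, x$specificity, x$accuracy, x$precision))
  invisible(x)
}

#' Collapse per-sample labels to one majority-vote label per second
#'
#' Optional coarser evaluation granularity: each full one-second block
#' becomes 1 when at least half its samples are labelled 1. A trailing
#' partial block is voted over the samples it has.
#'
#' @param labels a [label_vector()].
#' @return a [label_vector()] at 1 Hz.
#' @export
collapse_per_second <- function(labels) {
  stopifnot(inherits(labels, "label_vector"))
  block <- ceiling(labels$fs)
  grp <- (seq_along(labels$values) - 1L) %/% block
  means <- tapply(labels$values, grp, mean)
  label_vector(as.integer(means >= 0.5), fs = 1)
}

#' Percentile ROC sweep for the adaptive and Hilbert methods
#'
#' Runs the full bout-detection pipeline at each percentile of the grid,
#' converts the detected bouts to labels at the reference rate and compares
#' them with the reference, yielding one (FPR, TPR) point per percentile.
#'
#' @param recordings single [imu_recording()] or `list(left=, right=)`.
#' @param reference reference [label_vector()] spanning the recording.
#' @param method `"adaptive"` or `"hilbert"`.
#' @param grid percentile values in (0, 50]; the default is 1 followed by
#'   2.5 to 50 in steps of 2.5.
#' @param eparams an [enhancement_params()].
#' @param gparams a [grouping_params()] or NULL for the configuration
#'   default.
#' @param source `"gyro"` or `"acc"`.
#' @return an object of class `roc_curve`: a data frame with columns
#'   `percentile`, `tpr`, `fpr` plus `method` and `config` attributes.
#' @export
roc_sweep <- function(recordings, reference,
                      method = c("adaptive", "hilbert"),
                      grid = c(1, seq(2.5, 50, by = 2.5)),
                      eparams = enhancement_params(), gparams = NULL,
                      source = c("gyro", "acc")) {
  method <- match.arg(method)
  source <- match.arg(source)
  stopifnot(inherits(reference, "label_vector"))
  if (length(grid) == 0L) stop("empty percentile grid")
  if (any(grid <= 0 | grid > 50)) stop("percentile grid must lie in (0, 50]")
  duration <- length(reference$values) / reference$fs
  config <- if (inherits(recordings, "imu_recording")) "single_imu" else "dual_imu"
  rows <- lapply(grid, function(p) {
    spec <- threshold_spec(method, percentile = p)
    bouts <- detect_walking_bouts(recordings, spec, eparams, gparams,
                                  source = source)
    labs <- bouts_to_labels(bouts, duration = duration, fs = reference$fs)
    cm <- confusion_metrics(labs, reference)
    data.frame(percentile = p, tpr = cm$sensitivity,
               fpr = 1 - cm$specificity)
  })
  out <- do.call(rbind, rows)
  structure(out, method = method, config = config,
            class = c("roc_curve", "data.frame"))
}
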