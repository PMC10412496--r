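#' Construct a foot-worn IMU recording
#'
#' Container for raw multi-axis samples from one foot-mounted inertial
#' sensor. At least one of the gyroscope or accelerometer channels must be
#' present. Units are fixed by contract: angular velocity in deg/s,
#' acceleration in g; no unit auto-detection is performed because the
#' downstream fixed amplitude thresholds (100 deg/s, 0.5 g) are unit-bound.
#'
#' @param t numeric vector of strictly increasing sample times in seconds.
#' @param fs nominal sampling rate in Hz; must agree with the median sample
#'   interval within 1%.
#' @param gyro optional n x 3 numeric matrix of angular velocity
#'   (roll, pitch, yaw) in deg/s.
#' @param acc optional n x 3 numeric matrix of acceleration in g.
#' @param side which foot the sensor is mounted on: `"left"`, `"right"` or
#'   `"unspecified"`.
#' @return an object of class `imu_recording`.
#' @export
imu_recording <- function(t, fs, gyro = NULL, acc = NULL,
                          side = c("unspecified", "left", "right")) {
  side <- match.arg(side)
  t <- as.numeric(t)
  if (length(t) < 2L) stop("recording needs at least two samples")
  if (any(!is.finite(t))) stop("non-finite sample times")
  if (any(diff(t) <= 0)) stop("sample times must be strictly increasing")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("'fs' must be a positive scalar")
  }
  if (is.null(gyro) && is.null(acc)) {
    stop("at least one of 'gyro' or 'acc' must be present")
  }
  chk <- function(m, name) {
    if (is.null(m)) return(NULL)
    m <- as.matrix(m)
    if (ncol(m) != 3L) stop("'", name, "' must have 3 columns")
    if (nrow(m) != length(t)) stop("'", name, "' length differs from 't'")
    if (any(!is.finite(m))) stop("non-finite values in '", name, "'")
    storage.mode(m) <- "double"
    m
  }
  gyro <- chk(gyro, "gyro")
  acc <- chk(acc, "acc")
  dt <- stats::median(diff(t))
  if (abs(dt - 1 / fs) > 0.01 / fs) {
    stop("'fs' inconsistent with median sample interval (", signif(1 / dt, 6),
         " Hz observed)")
  }
  structure(list(t = t, fs = fs, gyro = gyro, acc = acc, side = side),
            class = "imu_recording")
}

#' @export
print.imu_recording <- function(x, ...) {
  chans <- c(if (!is.null(x$gyro)) "gyro", if (!is.null(x$acc)) "acc")
  cat(sprintf("<imu_recording> %s foot, %d samples @ %g Hz (%.1f s), channels: %s\n",
              x$side, length(x$t), x$fs, diff(range(x$t)),
              paste(chans, collapse = "+")))
  invisible(x)
}

#' Construct a per-sample binary locomotion label vector
#'
#' @param values vector of 0/1 labels (0 = no locomotion, 1 = locomotion).
#' @param fs label rate in Hz.
#' @return an object of class `label_vector`.
#' @export
label_vector <- function(values, fs) {
  values <- as.integer(values)
  if (length(values) == 0L) stop("empty label vector")
  if (any(is.na(values)) || !all(values %in% c(0L, 1L))) {
    stop("labels must be binary 0/1")
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("'fs' must be a positive scalar")
  }
  structure(list(values = values, fs = as.numeric(fs)), class = "label_vector")
}

#' @export
print.label_vector <- function(x, ...) {
  cat(sprintf("<label_vector> %d samples @ %g Hz, %.1f%% locomotion\n",
              length(x$values), x$fs, 100 * mean(x$values)))
  invisible(x)
}

#' Construct a walking bout
#'
#' A contiguous period of locomotion delimited by its member stride or step
#' event times. Bout boundaries equal the first and last member event time.
#'
#' @param events ordered stride/step event times in seconds.
#' @param config sensor configuration that produced the bout.
#' @param source signal the events were detected on.
#' @return an object of class `walking_bout` with fields `start`, `end`,
#'   `events`, `config`, `source`.
#' @export
walking_bout <- function(events, config = c("single_imu", "dual_imu"),
                         source = c("gyro", "acc")) {
  config <- match.arg(config)
  source <- match.arg(source)
  events <- as.numeric(events)
  if (length(events) == 0L) stop("a walking bout needs at least one event")
  if (is.unsorted(events)) stop("bout events must be ordered")
  structure(list(start = events[1L], end = events[length(events)],
                 events = events, config = config, source = source),
            class = "walking_bout")
}

#' @export
print.walking_bout <- function(x, ...) {
  cat(sprintf("<walking_bout> [%.2f, %.2f] s, %d events (%s, %s)\n",
              x$start, x$end, length(x$events), x$config, x$source))
  invisible(x)
}

default_column_map <- function() {
  list(time = "time",
       gyro = c("gyro_x", "gyro_y", "gyro_z"),
       acc = c("acc_x", "acc_y", "acc_z"))
}

#' Read a raw IMU recording from CSV
#'
#' The CSV dialect is user-mapped: `column_map` names the time column and the
#' three gyroscope and/or accelerometer columns, so any export dialect can be
#' ingested. Values are taken as-is in deg/s and g.
#'
#' @param path CSV file with a header row.
#' @param fs sampling rate in Hz.
#' @param column_map list with entries `time` (single column name) and at
#'   least one of `gyro`, `acc` (each three column names). Defaults to
#'   `time, gyro_x..z, acc_x..z`, using whichever channels the file has.
#' @param side sensor side passed to [imu_recording()].
#' @return an [imu_recording()].
#' @export
read_recording <- function(path, fs, column_map = NULL,
                           side = c("unspecified", "left", "right")) {
  side <- match.arg(side)
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (is.null(column_map)) {
    cm <- default_column_map()
    if (!all(cm$gyro %in% names(df))) cm$gyro <- NULL
    if (!all(cm$acc %in% names(df))) cm$acc <- NULL
    column_map <- cm
  }
  if (is.null(column_map$time)) stop("column_map must name a 'time' column")
  grab <- function(cols) {
    if (is.null(cols)) return(NULL)
    miss <- setdiff(cols, names(df))
    if (length(miss)) stop("mapped column(s) missing from ", path, ": ",
                           paste(miss, collapse = ", "))
    as.matrix(df[cols])
  }
  if (!column_map$time %in% names(df)) {
    stop("mapped column(s) missing from ", path, ": ", column_map$time)
  }
  imu_recording(t = df[[column_map$time]], fs = fs,
                gyro = grab(column_map$gyro), acc = grab(column_map$acc),
                side = side)
}

#' Write an IMU recording to CSV
#'
#' Columns are `time` plus `gyro_x..z` and/or `acc_x..z` for the channels
#' present; the counterpart of [read_recording()] with the default map.
#'
#' @param recording an [imu_recording()].
#' @param path output CSV path.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "imu_recording"))
  df <- data.frame(time = recording$t)
  if (!is.null(recording$gyro)) {
    df[c("gyro_x", "gyro_y", "gyro_z")] <- recording$gyro
  }
  if (!is.null(recording$acc)) {
    df[c("acc_x", "acc_y", "acc_z")] <- recording$acc
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

bout_sidecar_path <- function(path) {
  paste0(sub("\\.csv$", "", path), ".events.json")
}

#' Write walking bouts to CSV with a JSON event sidecar
#'
#' The CSV holds one row per bout (`bout_id, start_s, end_s, n_events,
#' config, source`); the full per-bout event time lists go to a JSON sidecar
#' next to the CSV (`<path stem>.events.json`).
#'
#' @param bouts list of [walking_bout()] objects (may be empty).
#' @param path output CSV path.
#' @return the CSV path, invisibly.
#' @export
write_bouts <- function(bouts, path) {
  stopifnot(all(vapply(bouts, inherits, logical(1), "walking_bout")))
  df <- data.frame(bout_id = integer(0), start_s = numeric(0),
                   end_s = numeric(0), n_events = integer(0),
                   config = character(0), source = character(0))
  if (length(bouts)) {
    df <- data.frame(
      bout_id = seq_along(bouts),
      start_s = vapply(bouts, `[[`, numeric(1), "start"),
      end_s = vapply(bouts, `[[`, numeric(1), "end"),
      n_events = vapply(bouts, function(b) length(b$events), integer(1)),
      config = vapply(bouts, `[[`, character(1), "config"),
      source = vapply(bouts, `[[`, character(1), "source"))
  }
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(lapply(bouts, `[[`, "events"), bout_sidecar_path(path),
                       digits = NA)
  invisible(path)
}

#' Read walking bouts written by [write_bouts()]
#'
#' @param path CSV path previously passed to [write_bouts()]; the JSON event
#'   sidecar must sit next to it.
#' @return list of [walking_bout()] objects.
#' @export
read_bouts <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  events <- lapply(jsonlite::read_json(bout_sidecar_path(path)),
                   function(e) unlist(e, use.names = FALSE))
  if (nrow(df) == 0L) return(list())
  lapply(seq_len(nrow(df)), function(i) {
    walking_bout(as.numeric(events[[i]]), config = df$config[i],
                 source = df$source[i])
  })
}

#' Read or write per-sample locomotion labels
#'
#' One CSV column of 0/1 values; the header records the label rate as
#' `label_fs<rate>` so the file is self-describing.
#'
#' @param path CSV path.
#' @param labels a [label_vector()] (writing only).
#' @return [label_vector()] for `read_labels`; the path invisibly for
#'   `write_labels`.
#' @export
write_labels <- function(labels, path) {
  stopifnot(inherits(labels, "label_vector"))
  df <- data.frame(x = labels$values)
  names(df) <- sprintf("label_fs%g", labels$fs)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.csv(path)
  m <- regmatches(names(df)[1], regexec("^label_fs([0-9.]+)$", names(df)[1]))[[1]]
  if (length(m) != 2L) stop("label file header does not record a rate: ", path)
  vals <- df[[1]]
  if (any(is.na(vals)) || !all(vals %in% c(0, 1))) {
    stop("non-binary value in label file: ", path)
  }
  label_vector(vals, fs = as.numeric(m[2]))
}
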