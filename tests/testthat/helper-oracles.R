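# Shared oracles and fixture builders. These deliberately re-derive results
# by brute force or closed form, independent of the implementation paths
# they check.

# wrap a plain numeric vector as an enhanced signal for peak-stage tests
make_signal <- function(values, fs = 40, source = "gyro") {
  structure(list(values = as.numeric(values), fs = fs, source = source),
            class = "enhanced_signal")
}

# type-7 quantile by the closed-rank linear-interpolation formula
quantile_type7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  if (lo >= n) return(x[n])
  x[lo] + (h - lo) * (x[lo + 1] - x[lo])
}

# replay the adaptive-gap rule over one contiguous block of event times;
# returns TRUE when every internal gap is admissible, plus the final gap
# limit at the block's end
replay_block <- function(ev, params) {
  ok <- TRUE
  for (j in seq_along(ev)[-1]) {
    th <- if (j - 1 >= 2) {
      min(params$update_offset + mean(diff(ev[1:(j - 1)])), params$gap_cap)
    } else {
      params$init_gap
    }
    if (ev[j] - ev[j - 1] > th) ok <- FALSE
  }
  th_end <- if (length(ev) >= 2) {
    min(params$update_offset + mean(diff(ev)), params$gap_cap)
  } else {
    params$init_gap
  }
  list(ok = ok, th_end = th_end)
}

# brute-force grouping oracle: enumerate every contiguous partition of the
# event times and keep those satisfying the adaptive-gap rule inside each
# block and a rule-exceeding gap at each block boundary
brute_force_group <- function(times, params) {
  n <- length(times)
  if (n == 0) return(list())
  if (n == 1) return(list(times))
  valid <- list()
  for (mask in 0:(2^(n - 1) - 1)) {
    cuts <- which(bitwAnd(mask, 2^(0:(n - 2))) > 0)
    bounds <- c(0, cuts, n)
    blocks <- lapply(seq_len(length(bounds) - 1), function(i) {
      times[(bounds[i] + 1):bounds[i + 1]]
    })
    ok <- TRUE
    for (i in seq_along(blocks)) {
      rb <- replay_block(blocks[[i]], params)
      if (!rb$ok) { ok <- FALSE; break }
      if (i < length(blocks)) {
        gap <- blocks[[i + 1]][1] - blocks[[i]][length(blocks[[i]])]
        if (gap <= rb$th_end) { ok <- FALSE; break }
      }
    }
    if (ok) valid[[length(valid) + 1]] <- blocks
  }
  stopifnot(length(valid) == 1) # the rule admits exactly one partition
  valid[[1]]
}

# direct O(n*m) correlation with the analytic gaus2 kernel (classic CWT
# amplitude convention), valid where the kernel lies fully inside the series
direct_gaus2_response <- function(x, scale, idx) {
  L <- ceiling(5 * scale)
  j <- -L:L
  k <- (2 - 4 * (j / scale)^2) * exp(-(j / scale)^2) /
    sqrt(3 * sqrt(pi / 2)) / sqrt(scale)
  vapply(idx, function(i) sum(x[i + j] * k), numeric(1))
}

# labels -> half-open [start, end) intervals on the sample grid
labels_to_intervals <- function(labels) {
  r <- rle(labels$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  on <- r$values == 1
  data.frame(start = (starts[on] - 1) / labels$fs, end = ends[on] / labels$fs)
}

# confusion counts by explicit elementwise loop (hand-count oracle)
count_confusion <- function(p, r) {
  tp <- tn <- fp <- fn <- 0
  for (i in seq_along(p)) {
    if (p[i] == 1 && r[i] == 1) tp <- tp + 1
    else if (p[i] == 0 && r[i] == 0) tn <- tn + 1
    else if (p[i] == 1 && r[i] == 0) fp <- fp + 1
    else fn <- fn + 1
  }
  c(TP = tp, TN = tn, FP = fp, FN = fn)
}
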