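test_that("candidate detection finds strict local maxima and plateau centres", {
  ps <- detect_candidate_peaks(make_signal(c(0, 1, 0)))
  expect_equal(ps$times, 1 / 40)
  expect_equal(ps$amplitudes, 1)
  expect_equal(ps$method, "candidates")
  expect_equal(ps$threshold_value, -Inf)

  expect_length(detect_candidate_peaks(make_signal(0:20))$times, 0)
  expect_length(detect_candidate_peaks(make_signal(c(1, 0)))$times, 0)

  # plateau of three equal values resolves to its centre sample
  v <- c(0, 2, 5, 5, 5, 2, 0)
  ps <- detect_candidate_peaks(make_signal(v))
  expect_equal(ps$times, 3 / 40) # centre index 4, zero-based 3
  expect_equal(ps$amplitudes, 5)
})

test_that("a ten-cycle tone yields ten crest peaks at the analytic positions", {
  k <- 0:400
  ps <- detect_candidate_peaks(make_signal(sin(2 * pi * k / 40)))
  expect_length(ps$times, 10)
  expect_equal(ps$times, (seq(10, 370, by = 40)) / 40, tolerance = 1e-12)
})

test_that("fixed threshold keeps peaks at or above the unit-bound cut", {
  cand <- peak_set(1:4, c(50, 99, 100, 150), "candidates", source = "gyro")
  sel <- select_fixed(cand)
  expect_equal(sel$amplitudes, c(100, 150))
  expect_equal(sel$threshold_value, 100)

  none <- select_fixed(peak_set(1:2, c(10, 20), "candidates", source = "gyro"))
  expect_length(none$times, 0)

  acc <- peak_set(1:2, c(0.4, 0.6), "candidates", source = "acc")
  sel_acc <- select_fixed(acc)
  expect_equal(sel_acc$amplitudes, 0.6)
  expect_equal(sel_acc$threshold_value, 0.5)
})

test_that("adaptive threshold equals the type-7 percentile of survivors", {
  cand <- peak_set(1:10, seq(100, 190, by = 10), "candidates", source = "gyro")
  sel <- select_adaptive(cand, threshold_spec("adaptive", percentile = 10))
  expect_equal(sel$threshold_value, 109)
  expect_equal(sel$threshold_value,
               quantile_type7(seq(100, 190, by = 10), 0.10))
  expect_length(sel$times, 9)

  one <- peak_set(1, 123, "candidates", source = "gyro")
  sel1 <- select_adaptive(one)
  expect_equal(sel1$threshold_value, 123)
  expect_length(sel1$times, 1)

  empty <- select_adaptive(peak_set(1:2, c(10, 20), "candidates",
                                    source = "gyro"))
  expect_length(empty$times, 0)
  expect_equal(empty$threshold_value, 100)
})

test_that("selection is nested in the percentile and never below fixed", {
  set.seed(21)
  for (rep in 1:20) {
    amps <- runif(30, 50, 600)
    cand <- peak_set(seq_along(amps), amps, "candidates", source = "gyro")
    s10 <- select_adaptive(cand, threshold_spec("adaptive", percentile = 10))
    s50 <- select_adaptive(cand, threshold_spec("adaptive", percentile = 50))
    expect_true(all(s50$times %in% s10$times))
    sf <- select_fixed(cand)
    expect_true(all(s10$times %in% sf$times))
    expect_gte(s10$threshold_value, 100)
    expect_true(all(s10$times %in% cand$times)) # no peak invention
  }
})

test_that("Hilbert pre-selection extracts sustained high-envelope periods", {
  expect_equal(nrow(hilbert_preselect(make_signal(rep(0, 400)))), 0)

  # 10 s tone burst, amplitude 300, inside 30 s of silence
  t <- (0:1199) / 40
  x <- ifelse(t >= 10 & t < 20, 300 * sin(2 * pi * 1 * t), 0)
  per <- hilbert_preselect(make_signal(x))
  expect_equal(nrow(per), 1)
  expect_lt(abs(per$start - 10), 0.5)
  expect_lt(abs(per$end - 20), 0.5)

  # two bursts separated by less than the merge gap become one period
  x2 <- ifelse((t >= 5 & t < 10) | (t >= 12 & t < 17),
               300 * sin(2 * pi * 1 * t), 0)
  per2 <- hilbert_preselect(make_signal(x2))
  expect_equal(nrow(per2), 1)
})

test_that("Hilbert selection restricts to pre-selected periods", {
  t <- (0:1199) / 40
  x <- ifelse(t >= 10 & t < 20, 300 * sin(2 * pi * 1 * t), 0)
  sig <- make_signal(x)
  cand <- detect_candidate_peaks(sig)

  # candidates forced outside every period -> empty set
  outside <- peak_set(c(1, 2, 25), c(500, 400, 300), "candidates",
                      source = "gyro")
  sel_out <- select_hilbert(outside, make_signal(rep(0, 400)))
  expect_length(sel_out$times, 0)

  sel <- select_hilbert(cand, sig, threshold_spec("hilbert", percentile = 1))
  in_burst <- cand$times[cand$times >= 10 & cand$times < 20 &
                           cand$amplitudes > 100]
  expect_true(all(in_burst %in% sel$times))

  sel50 <- select_hilbert(cand, sig, threshold_spec("hilbert", percentile = 50))
  expect_true(all(sel50$times %in% sel$times))
})

test_that("threshold specifications validate their ranges", {
  expect_error(threshold_spec("adaptive", percentile = 60), "\\(0, 50\\]")
  expect_error(threshold_spec("adaptive", percentile = 0), "\\(0, 50\\]")
  expect_error(threshold_spec("fixed", fixed_gyro = -5), "> 0")
  expect_equal(threshold_spec("adaptive")$percentile, 10)
  expect_equal(threshold_spec("hilbert")$percentile, 1)
})
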