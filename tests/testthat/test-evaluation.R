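test_that("bout intervals rasterize to half-open per-sample labels", {
  b <- walking_bout(c(2, 3, 5), "single_imu", "gyro")
  lv <- bouts_to_labels(list(b), duration = 10, fs = 40)
  expect_equal(sum(lv$values), 120)
  expect_equal(lv$values[80], 0L)  # sample 79 at 1.975 s
  expect_equal(lv$values[81], 1L)  # sample 80 at 2.000 s
  expect_equal(lv$values[201], 0L) # sample 200 at 5.000 s excluded

  expect_equal(sum(bouts_to_labels(list(), 10, 40)$values), 0)

  two <- list(walking_bout(c(0, 1, 2), "single_imu", "gyro"),
              walking_bout(c(2, 3, 4), "single_imu", "gyro"))
  one <- list(walking_bout(c(0, 2, 4), "single_imu", "gyro"))
  expect_equal(bouts_to_labels(two, 6, 40)$values,
               bouts_to_labels(one, 6, 40)$values)

  late <- walking_bout(c(8, 9, 11), "single_imu", "gyro")
  expect_error(bouts_to_labels(list(late), 10, 40), "outside")
})

test_that("rasterized labels invert to the generating interval set", {
  set.seed(17)
  for (rep in 1:10) {
    n_iv <- sample(1:4, 1)
    starts <- sort(sample(0:80, n_iv)) / 4
    lens <- sample(4:20, n_iv, replace = TRUE) / 4
    ends <- pmin(starts + lens, 25)
    keep <- logical(n_iv) # drop draws overlapping or touching a kept one
    last_end <- -Inf
    for (i in seq_len(n_iv)) {
      if (starts[i] > last_end) {
        keep[i] <- TRUE
        last_end <- ends[i]
      }
    }
    iv <- data.frame(start = starts[keep], end = ends[keep])
    bouts <- lapply(seq_len(nrow(iv)), function(i) {
      b <- walking_bout(c(iv$start[i], iv$end[i]), "single_imu", "gyro")
      b
    })
    lv <- bouts_to_labels(bouts, duration = 25, fs = 4)
    expect_equal(labels_to_intervals(lv), iv, ignore_attr = TRUE)
  }
})

test_that("confusion metrics match hand counts and handle degeneracy", {
  cm <- confusion_metrics(label_vector(c(1, 1, 0, 0), 40),
                          label_vector(c(1, 0, 1, 0), 40))
  expect_equal(unlist(cm[c("TP", "FP", "FN", "TN")]), c(TP = 1, FP = 1,
                                                        FN = 1, TN = 1))
  expect_equal(cm$sensitivity, 0.5)
  expect_equal(cm$specificity, 0.5)
  expect_equal(cm$accuracy, 0.5)
  expect_equal(cm$precision, 0.5)

  same <- label_vector(c(0, 1, 1, 0, 1), 40)
  cm2 <- confusion_metrics(same, same)
  expect_equal(c(cm2$sensitivity, cm2$specificity, cm2$accuracy,
                 cm2$precision), rep(1, 4))

  cm3 <- confusion_metrics(label_vector(c(1, 0, 0, 0), 40),
                           label_vector(c(0, 0, 0, 0), 40))
  expect_true(is.nan(cm3$sensitivity))
  expect_equal(cm3$specificity, 0.75)

  expect_error(confusion_metrics(label_vector(c(0, 1), 40),
                                 label_vector(c(0, 1, 1), 40)), "lengths")
  expect_error(confusion_metrics(label_vector(c(0, 1), 40),
                                 label_vector(c(0, 1), 100)), "rates differ")
})

test_that("confusion metrics agree with the loop oracle on all 4-sample pairs", {
  for (pi in 0:15) {
    for (ri in 0:15) {
      p <- as.integer(intToBits(pi))[1:4]
      r <- as.integer(intToBits(ri))[1:4]
      cm <- confusion_metrics(label_vector(p, 40), label_vector(r, 40))
      want <- count_confusion(p, r)
      expect_equal(c(TP = cm$TP, TN = cm$TN, FP = cm$FP, FN = cm$FN), want)
      expect_equal(cm$TP + cm$TN + cm$FP + cm$FN, 4) # conservation
    }
  }
})

test_that("swapping prediction and reference swaps FP with FN", {
  set.seed(23)
  p <- label_vector(rbinom(500, 1, 0.4), 40)
  r <- label_vector(rbinom(500, 1, 0.6), 40)
  a <- confusion_metrics(p, r)
  b <- confusion_metrics(r, p)
  expect_equal(a$FP, b$FN)
  expect_equal(a$FN, b$FP)
  expect_equal(a$TP, b$TP)
  expect_equal(a$sensitivity, b$precision)
  expect_equal(a$precision, b$sensitivity)
})

test_that("per-second collapse takes the majority vote", {
  lv <- label_vector(c(1, 1, 1, 0, 0, 0, 0, 1, 1, 1, 1, 0), fs = 4)
  out <- collapse_per_second(lv)
  expect_equal(out$values, c(1L, 0L, 1L))
  expect_equal(out$fs, 1)
  # exact tie votes positive
  expect_equal(collapse_per_second(label_vector(c(1, 1, 0, 0), 4))$values, 1L)
})

test_that("ROC sweep is consistent, bounded and deterministic", {
  sim <- simulate_recording(sim_config(seed = 13, duration = 120, n_bouts = 1,
                                       strides_per_bout = 20))
  ref <- truth_labels(sim$truth, 120, 40)

  single <- roc_sweep(sim$recording, ref, "adaptive", grid = 10)
  spec <- threshold_spec("adaptive", percentile = 10)
  bouts <- detect_walking_bouts(sim$recording, spec)
  cm <- confusion_metrics(bouts_to_labels(bouts, 120, 40), ref)
  expect_equal(single$tpr, cm$sensitivity)
  expect_equal(single$fpr, 1 - cm$specificity)

  grid <- c(1, 10, 25, 40)
  roc <- roc_sweep(sim$recording, ref, "adaptive", grid = grid)
  expect_true(all(roc$tpr >= 0 & roc$tpr <= 1))
  expect_true(all(roc$fpr >= 0 & roc$fpr <= 1))
  # appending grid points preserves earlier points bit-for-bit
  roc2 <- roc_sweep(sim$recording, ref, "adaptive", grid = c(grid, 50))
  expect_identical(roc[, c("tpr", "fpr")], roc2[1:4, c("tpr", "fpr")])

  expect_error(roc_sweep(sim$recording, ref, "adaptive", grid = numeric(0)),
               "empty")
  expect_error(roc_sweep(sim$recording, ref, "adaptive", grid = c(10, 60)),
               "\\(0, 50\\]")
})
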