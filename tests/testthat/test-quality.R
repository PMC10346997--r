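test_that("peak/valley detection counts extrema of known waveforms", {
  t6 <- (0:749) / 125
  pk <- detect_peaks_valleys(sin(2 * pi * 1.2 * t6), 125)
  expect_length(pk$peak_indices, 7L)       # maxima of 1.2 Hz over 6 s
  expect_length(pk$valley_indices, 7L)
  expect_equal(pk$intervals_s, rep(1 / 1.2, 6), tolerance = 0.02)

  expect_length(detect_peaks_valleys(rep(1, 800), 125)$peak_indices, 0L)

  sim <- synth_record(synth_params(duration_s = 8, hr_bpm = 75,
                                   artifact_ratio = 0, noise_sd = 0,
                                   drift_amp = 0, seed = 1))
  pk75 <- detect_peaks_valleys(sim$record$ppg, 125)
  expect_length(pk75$peak_indices, 10L)    # 75 bpm over 8 s
  expect_equal(mean(pk75$intervals_s), 0.8, tolerance = 0.01)

  expect_error(detect_peaks_valleys(rnorm(100), 125), "too short")
})

test_that("pulsatility accepts only near-balanced extremum counts", {
  expect_true(check_pulsatility(make_peak_set(7, 7)))
  expect_true(check_pulsatility(make_peak_set(7, 8)))
  expect_false(check_pulsatility(make_peak_set(7, 10)))
  expect_false(check_pulsatility(make_peak_set(2, 2)))  # too few beats
})

test_that("interval consistency implements the 10% consecutive-difference rule", {
  expect_true(check_interval_consistency(c(0.80, 0.80, 0.80)))
  expect_true(check_interval_consistency(c(0.80, 0.87, 0.80)))
  expect_false(check_interval_consistency(c(0.80, 0.95)))
  expect_false(check_interval_consistency(0.8))        # single interval
  expect_false(check_interval_consistency(numeric(0)))
})

test_that("per-cycle statistics match analytic values", {
  # full sine cycles: kurtosis 3/2, zero mean
  x <- sin(2 * pi * 2 * (0:999) / 125)
  pk <- detect_peaks_valleys(x, 125)
  st <- window_statistics(x, pk)
  expect_length(st$kurtosis, length(pk$peak_indices) - 1L)
  expect_equal(st$kurtosis, rep(1.5, length(st$kurtosis)), tolerance = 0.05)
  expect_equal(st$mean, rep(0, length(st$mean)), tolerance = 0.02)

  # near-constant cycle: degenerate kurtosis fails the gate
  flat <- structure(list(kurtosis = NaN, mean = 0, std = 0),
                    class = "window_stats")
  expect_false(check_statistics(flat))
  empty <- structure(list(kurtosis = numeric(0), mean = numeric(0),
                          std = numeric(0)), class = "window_stats")
  expect_false(check_statistics(empty))

  # excess convention shifts by 3
  st_ex <- window_statistics(x, pk, kurtosis_convention = "excess")
  expect_equal(st_ex$kurtosis, st$kurtosis - 3)

  expect_error(window_statistics(x, make_peak_set(1, 1)), "two detected")
})

test_that("statistical gating respects the threshold bands", {
  st <- structure(list(kurtosis = c(2, 2.5), mean = c(0, 0.1),
                       std = c(1, 1.1)), class = "window_stats")
  expect_true(check_statistics(st))
  st$kurtosis[2] <- 9
  expect_false(check_statistics(st))
})

test_that("quality assessment gates windows as a whole", {
  sim <- synth_record(synth_params(duration_s = 8, hr_bpm = 72,
                                   artifact_ratio = 0, noise_sd = 0.02,
                                   drift_amp = 0.1, seed = 2))
  q <- assess_quality(prefilter(sim$record$ppg), 125)
  expect_identical(q$sqt, 1L)
  expect_true(q$pulsatility_ok && q$intervals_ok && q$stats_ok)

  # heavy corruption: 5x white noise + strong drift
  noisy <- synth_record(synth_params(duration_s = 8, hr_bpm = 72,
                                     artifact_ratio = 0, noise_sd = 5,
                                     drift_amp = 3, seed = 2))
  q_bad <- assess_quality(prefilter(noisy$record$ppg), 125)
  expect_identical(q_bad$sqt, 0L)
  expect_false(q_bad$pulsatility_ok && q_bad$intervals_ok && q_bad$stats_ok)

  q0 <- assess_quality(rep(0, 1000), 125)
  expect_identical(q0$sqt, 0L)

  # the token is the conjunction of the three checks
  for (q_i in list(q, q_bad, q0)) {
    expect_identical(q_i$sqt == 1L,
                     q_i$pulsatility_ok && q_i$intervals_ok && q_i$stats_ok)
  }
})

test_that("quality label is invariant to positive affine amplitude changes", {
  sim <- synth_record(synth_params(duration_s = 8, hr_bpm = 80,
                                   artifact_ratio = 1, seed = 4))
  w <- prefilter(sim$record$ppg)
  base <- assess_quality(w, 125)
  set.seed(10)
  for (i in 1:5) {
    c_ <- runif(1, 0.01, 100)
    d_ <- runif(1, -50, 50)
    scaled <- assess_quality(c_ * w + d_, 125)
    expect_identical(scaled$sqt, base$sqt)
    expect_identical(scaled$peaks$peak_indices, base$peaks$peak_indices)
  }
})

test_that("repeated assessment of one window is identical (pure function)", {
  sim <- synth_record(synth_params(duration_s = 8, seed = 6))
  w <- prefilter(sim$record$ppg)
  expect_identical(assess_quality(w, 125), assess_quality(w, 125))
})

test_that("threshold calibration recovers bands covering clean cycles", {
  clean <- lapply(1:20, function(i)
    prefilter(synth_record(synth_params(duration_s = 8, artifact_ratio = 0,
                                        seed = 100 + i))$record$ppg))
  thr <- calibrate_thresholds(clean, 125)
  expect_named(thr, c("kurtosis", "mean", "std"))
  for (b in thr) expect_lt(b[1], b[2])
  # the pulse template's cycle kurtosis (~1.8) lies inside the fitted band
  expect_true(thr$kurtosis[1] < 1.8 && 1.8 < thr$kurtosis[2] + 0.2)
})
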