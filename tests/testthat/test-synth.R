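test_that("generation is deterministic in the seed and leaves no RNG trace", {
  a <- synth_record(synth_params(duration_s = 10, seed = 33))
  b <- synth_record(synth_params(duration_s = 10, seed = 33))
  expect_identical(a$record$ppg, b$record$ppg)
  expect_identical(a$record$accel, b$record$accel)
  c_ <- synth_record(synth_params(duration_s = 10, seed = 34))
  expect_false(identical(a$record$ppg, c_$record$ppg))

  set.seed(123); before <- rnorm(5)
  set.seed(123); invisible(synth_record(synth_params(duration_s = 5, seed = 1)))
  expect_identical(rnorm(5), before)   # generator restored the RNG state
})

test_that("the artifact ratio and accelerometer coupling are exact by construction", {
  sim <- synth_record(synth_params(duration_s = 20, artifact_ratio = 2,
                                   accel_noise_sd = 0, noise_sd = 0,
                                   drift_amp = 0, seed = 12))
  rms <- function(x) sqrt(mean(x^2))
  expect_equal(rms(sim$artifact) / rms(sim$clean), 2, tolerance = 0.01)
  for (a in 1:3) {
    expect_equal(abs(cor(sim$record$accel[, a], sim$artifact)), 1,
                 tolerance = 1e-12)
  }
  # and the record is the sum of its parts
  expect_equal(sim$record$ppg, sim$clean + sim$artifact + sim$drift,
               tolerance = 1e-12)
})

test_that("a clean constant-rate record has its spectral peak at the true HR", {
  sim <- synth_record(synth_params(duration_s = 8, hr_bpm = 72,
                                   artifact_ratio = 0, noise_sd = 0,
                                   drift_amp = 0, seed = 2))
  est <- pick_hr(dft_spectrum(sim$record$ppg, 125))
  expect_equal(est$hr_bpm, 72, tolerance = 0.5)
  expect_equal(window_true_hr(sim, 8, 2), 72)
})

test_that("a piecewise-linear HR profile is followed", {
  prof <- cbind(c(0, 30), c(60, 120))
  sim <- synth_record(synth_params(duration_s = 30, hr_bpm = prof,
                                   artifact_ratio = 0, noise_sd = 0,
                                   drift_amp = 0, seed = 3))
  expect_equal(sim$hr_bpm[1], 60)
  expect_equal(sim$hr_bpm[length(sim$hr_bpm)], 120, tolerance = 0.1)
  truth <- window_true_hr(sim, 8, 2)
  expect_true(all(diff(truth) > 0))
})

test_that("parameter validation rejects impossible settings", {
  expect_error(synth_params(hr_bpm = 300), "40, 180")
  expect_error(synth_params(artifact_ratio = -1), ">= 0")
  expect_error(synth_params(fs = 10, motion_freq_hz = 3, motion_harmonics = 3),
               "highest generated frequency")
})

test_that("batches draw per-record parameters and independent seeds", {
  sims <- synth_batch(5, ranges = list(hr_bpm = c(60, 100)), seed = 9,
                      duration_s = 8)
  hrs <- vapply(sims, function(s) s$params$hr_bpm, numeric(1))
  expect_true(all(hrs >= 60 & hrs <= 100))
  expect_gt(length(unique(round(hrs, 3))), 1L)
  expect_length(unique(vapply(sims, function(s) s$params$seed, integer(1))), 5L)
  # reproducible end to end
  sims2 <- synth_batch(5, ranges = list(hr_bpm = c(60, 100)), seed = 9,
                       duration_s = 8)
  expect_identical(sims[[3]]$record$ppg, sims2[[3]]$record$ppg)
})
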