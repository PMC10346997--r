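test_that("the magnitude spectrum localizes a known tone on a fine grid", {
  x <- sin(2 * pi * 1.25 * (0:999) / 125)
  sp <- dft_spectrum(x, 125, nfft = 16384)
  expect_lt(abs(sp$freqs[which.max(sp$mags)] - 1.25), 0.01)
  expect_true(all(sp$mags >= 0))
  expect_equal(sp$freqs[1], 0)
  expect_equal(sp$freqs[length(sp$freqs)], 62.5)

  # constant window: empty spectrum after mean removal
  spc <- dft_spectrum(rep(2, 100), 125, nfft = 256)
  expect_true(all(spc$mags < 1e-12))

  # Parseval (untapered, unpadded): one-sided energy equals nfft * sum(x^2)
  set.seed(4)
  y <- rnorm(256)
  y <- y - mean(y)
  spp <- dft_spectrum(y, 125, nfft = 256, taper = "none")
  e2 <- spp$mags[1]^2 + spp$mags[129]^2 + 2 * sum(spp$mags[2:128]^2)
  expect_equal(e2, 256 * sum(y^2), tolerance = 1e-8)

  expect_error(dft_spectrum(numeric(0), 125), "empty")
  expect_error(dft_spectrum(rnorm(100), 125, nfft = 50), "nfft")
})

test_that("the default grid is finer than half a bpm", {
  sp <- dft_spectrum(rnorm(1000), 125)
  expect_lte(diff(sp$freqs[1:2]), 0.5 / 60)
})

test_that("pick_hr takes the band argmax and converts to bpm", {
  x <- sin(2 * pi * 1.25 * (0:999) / 125)
  est <- pick_hr(dft_spectrum(x, 125))
  expect_equal(est$hr_bpm, 75, tolerance = 0.5)
  expect_equal(est$hr_bpm, 60 * est$peak_freq_hz)
  expect_false(est$tracked)
  expect_true(est$hr_bpm >= 42 && est$hr_bpm <= 210)
})

test_that("tracking confines the pick near the previous estimate", {
  # two tones: weak at 1.25 Hz, strong at 2.0 Hz
  x <- 0.5 * sin(2 * pi * 1.25 * (0:999) / 125) +
       1.0 * sin(2 * pi * 2.0 * (0:999) / 125)
  sp <- dft_spectrum(x, 125)
  tracked <- pick_hr(sp, prev_hr = 75)
  expect_equal(tracked$hr_bpm, 75, tolerance = 1)
  expect_true(tracked$tracked)
  free <- pick_hr(sp)
  expect_equal(free$hr_bpm, 120, tolerance = 1)

  # sub-band magnitude below the relative floor: concede to the global peak
  weak <- pick_hr(sp, prev_hr = 170, rel_floor = 0.2)
  expect_false(weak$tracked)
  expect_equal(weak$hr_bpm, 120, tolerance = 1)

  # empty tracking band: previous estimate carried forward
  carried <- pick_hr(sp, prev_hr = 300, max_jump_bpm = 5)
  expect_true(carried$carried)
  expect_equal(carried$hr_bpm, 300)
})

test_that("ties break toward the lower frequency", {
  freqs <- seq(0, 62.5, length.out = 8193)
  mags <- rep(0, 8193)
  i1 <- which.min(abs(freqs - 1.2)); i2 <- which.min(abs(freqs - 2.2))
  mags[c(i1, i2)] <- 1
  sp <- structure(list(freqs = freqs, mags = mags, fs = 125, nfft = 16384),
                  class = "hr_spectrum")
  expect_equal(pick_hr(sp, interp = FALSE, harmonic_ratio = 0)$peak_freq_hz,
               freqs[i1])
})

test_that("a strong half-frequency peak is preferred over its harmonic", {
  x <- 0.8 * sin(2 * pi * 1.5 * (0:999) / 125) +
       1.0 * sin(2 * pi * 3.0 * (0:999) / 125)
  est <- pick_hr(dft_spectrum(x, 125))
  expect_equal(est$hr_bpm, 90, tolerance = 1)     # 1.5 Hz, not 3 Hz
  est_off <- pick_hr(dft_spectrum(x, 125), harmonic_ratio = 0)
  expect_equal(est_off$hr_bpm, 180, tolerance = 1)
})

test_that("notch_mar removes the cadence tone and little else", {
  fs <- 125
  tt <- (0:1499) / fs
  beat <- sin(2 * pi * 1.2 * tt)
  artifact <- 1.5 * sin(2 * pi * 2.4 * tt)
  ppg <- beat + artifact
  accel <- cbind(artifact, 0, 0)
  out <- notch_mar(ppg, accel, fs)
  expect_false(attr(out, "noop"))
  expect_equal(attr(out, "motion_freq_hz"), 2.4, tolerance = 0.05)
  expect_length(out, length(ppg))

  band_power <- function(x, f0, bw = 0.24) {
    sp <- dft_spectrum(x, fs, taper = "none")
    sum(sp$mags[abs(sp$freqs - f0) <= bw]^2)
  }
  expect_lt(band_power(out, 2.4) / band_power(ppg, 2.4), 0.05)
  # HR peak survives
  est <- pick_hr(dft_spectrum(out, fs))
  expect_equal(est$hr_bpm, 72, tolerance = 2)

  # silent accelerometer: a declared no-op
  out0 <- notch_mar(ppg, matrix(0, length(ppg), 3), fs)
  expect_true(attr(out0, "noop"))
  expect_equal(as.numeric(out0), ppg)

  # white-noise PPG: only the notched band is touched
  set.seed(8)
  wn <- rnorm(1500)
  outw <- notch_mar(wn, accel, fs)
  expect_lt(1 - sum(outw^2) / sum(wn^2), 0.10)

  expect_error(notch_mar(ppg[1:100], accel[1:100, ], fs), "2 s")
})
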