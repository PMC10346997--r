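test_that("build_hankel matches its definition and covers every sample", {
  expect_identical(build_hankel(c(1, 2, 3, 4)), matrix(c(1, 2, 2, 3, 3, 4), 2, 3))

  set.seed(7)
  for (n in c(4L, 5L, 9L, 10L, 101L)) {
    x <- rnorm(n)
    H <- build_hankel(x)
    expect_equal(dim(H), c(ceiling(n / 2), n - ceiling(n / 2) + 1L))
    # Hankel property: constant along anti-diagonals
    expect_identical(H[-nrow(H), -1, drop = FALSE],
                     H[-1, -ncol(H), drop = FALSE])
    expect_identical(H[nrow(H), ncol(H)], x[n])   # last sample present
    expect_equal(hankel_to_series(H), x)
  }
  expect_error(build_hankel(1:3), "too short")
})

test_that("decomposition exposes rank, sorted energies and exact completeness", {
  # constant series: rank-1 trajectory matrix
  hs_const <- hankel_decompose(rep(3.5, 20))
  expect_gt(hs_const$d[1], 0)
  expect_lt(hs_const$d[2] / hs_const$d[1], 1e-12)
  expect_equal(component_series(hs_const, 1), rep(3.5, 20), tolerance = 1e-10)

  set.seed(11)
  x <- rnorm(80)
  hs <- hankel_decompose(x)
  expect_true(all(diff(hs$d) <= 1e-12))
  expect_equal(sum(hs$d^2), sum(build_hankel(x)^2), tolerance = 1e-12)

  # completeness: component series sum to the original series
  total <- Reduce(`+`, lapply(seq_along(hs$d), component_series, hsvd = hs))
  expect_equal(total, x, tolerance = 1e-8)
  expect_equal(reconstruct_series(hs, seq_along(hs$d)), x, tolerance = 1e-8)

  expect_error(component_series(hs, length(hs$d) + 1L), "out of range")
  expect_error(reconstruct_series(hs, integer(0)), "empty")
})

test_that("a pure sinusoid concentrates in its leading component pair", {
  x <- sin(2 * pi * 1.2 * (0:999) / 125)
  hs <- hankel_decompose(x)
  expect_gt(sum(hs$d[1:2]^2) / sum(hs$d^2), 0.99)
  recon <- reconstruct_series(hs, 1:2)
  expect_lt(sqrt(mean((recon - x)^2)) / sqrt(mean(x^2)), 1e-2)
})

test_that("pearson_corr handles the standard and degenerate cases", {
  set.seed(3)
  x <- rnorm(50)
  expect_equal(as.numeric(pearson_corr(x, x)), 1)
  expect_equal(as.numeric(pearson_corr(x, -x)), -1)
  tt <- (0:999) / 1000 * 8          # exactly 8 periods
  expect_lt(abs(pearson_corr(sin(2 * pi * tt), cos(2 * pi * tt))), 1e-6)
  r <- pearson_corr(rep(1, 10), rnorm(10))
  expect_identical(as.numeric(r), 0)
  expect_true(attr(r, "degenerate"))
})

test_that("component selection rejects acceleration-correlated components only", {
  fs <- 125
  tt <- (0:999) / fs
  sim <- synth_record(synth_params(duration_s = 8, hr_bpm = 72,
                                   artifact_ratio = 0, noise_sd = 0,
                                   drift_amp = 0, seed = 5))
  beat <- sim$record$ppg
  artifact <- sin(2 * pi * 2.4 * tt)
  artifact <- artifact * 2 * sqrt(mean(beat^2)) / sqrt(mean(artifact^2))
  ppg <- beat + artifact
  accel <- cbind(artifact, 0, 0)

  hs <- hankel_decompose(ppg)
  sel <- select_components(hs, accel, threshold = 0.5)
  expect_gte(length(sel$removed), 2L)
  # the removed components are the artifact carriers: strongly ax-correlated
  expect_true(all(abs(sel$corr_matrix[sel$removed, "ax"]) >= 0.9))
  expect_true(all(abs(sel$corr_matrix) <= 1))
  expect_setequal(c(sel$kept, sel$removed), seq_along(hs$d))

  # cleaning moves the window toward the clean beat, away from the corrupted
  clean <- reconstruct_series(hs, sel)
  expect_gt(cor(clean, beat), cor(clean, ppg))
  expect_gt(cor(clean, beat), 0.9)

  # silent accelerometer: nothing to reject
  sel0 <- select_components(hs, matrix(0, 1000, 3))
  expect_length(sel0$removed, 0L)
  expect_true(all(sel0$corr_matrix == 0))

  # weak coupling far below an extreme threshold: nothing removed
  set.seed(9)
  noisy_accel <- matrix(rnorm(3000), ncol = 3)
  sel1 <- select_components(hs, noisy_accel, threshold = 0.999)
  expect_length(sel1$removed, 0L)

  expect_error(select_components(hs, accel, threshold = 1.5), "threshold")
})

test_that("decomposition agrees with the brute-force oracle on short series", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    x <- rnorm(n)
    expect_equal(build_hankel(x), oracle_hankel(x), tolerance = 1e-12)
    hs <- hankel_decompose(x)
    kept <- sort(sample(seq_along(hs$d), sample(seq_along(hs$d), 1)))
    expect_equal(reconstruct_series(hs, kept), oracle_reconstruct(x, kept),
                 tolerance = 1e-10)
    i <- sample(seq_along(hs$d), 1)
    expect_equal(component_series(hs, i), oracle_reconstruct(x, i),
                 tolerance = 1e-10)
  }
})
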