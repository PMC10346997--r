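# Seeded synthetic PPG + accelerometer generator with ground truth.
#
# The generator emulates the signal structure the method assumes: a
# quasi-periodic pulsatile waveform (truncated harmonic series driven by an
# instantaneous heart-rate profile), low-frequency baseline drift, an additive
# motion artifact whose spectrum (cadence fundamental + harmonics) is shared
# with the acceleration channels, and white sensor noise.

#' Parameters for the synthetic record generator
#'
#' @param duration_s record length in seconds.
#' @param fs sampling rate in Hz; must exceed twice the highest generated
#'   frequency.
#' @param hr_bpm heart-rate profile: a single bpm value for a constant HR, or
#'   a two-column matrix/data.frame `(time_s, bpm)` interpolated
#'   piecewise-linearly. Must stay within 40-180 bpm.
#' @param pulse_shape amplitudes of the beat-template harmonics (fundamental
#'   first). The default `c(1, 0.4, 0.15)` gives the skewed systolic upstroke
#'   typical of a wrist PPG pulse.
#' @param motion_freq_hz cadence (step frequency) of the motion artifact in
#'   Hz; walking/running cadences fall in 0.5-3 Hz.
#' @param motion_harmonics number of artifact harmonics (fundamental
#'   included); amplitudes decay as 1/h, matching the harmonic-rich spectra
#'   of wrist accelerometry during gait.
#' @param artifact_ratio artifact RMS divided by pulsatile RMS (0 = clean).
#' @param drift_amp baseline-drift RMS relative to pulsatile RMS.
#' @param drift_cutoff_hz upper frequency of the baseline drift band.
#' @param noise_sd white-noise SD relative to pulsatile RMS.
#' @param accel_coupling per-axis gains coupling the artifact into the
#'   accelerometer channels.
#' @param accel_noise_sd independent accelerometer noise, relative to each
#'   axis's artifact RMS (kept small so accel-artifact correlations are near
#'   but not exactly +/-1).
#' @param seed integer seed; identical seeds give identical records.
#' @return A list of class `synth_params`.
#' @export
synth_params <- function(duration_s = 60, fs = 125, hr_bpm = 75,
                         pulse_shape = c(1, 0.4, 0.15),
                         motion_freq_hz = 2, motion_harmonics = 3,
                         artifact_ratio = 1, drift_amp = 0.5,
                         drift_cutoff_hz = 0.15, noise_sd = 0.05,
                         accel_coupling = c(1, 0.7, 0.4),
                         accel_noise_sd = 0.01, seed = 1L) {
  p <- list(duration_s = duration_s, fs = fs, hr_bpm = hr_bpm,
            pulse_shape = pulse_shape, motion_freq_hz = motion_freq_hz,
            motion_harmonics = motion_harmonics,
            artifact_ratio = artifact_ratio, drift_amp = drift_amp,
            drift_cutoff_hz = drift_cutoff_hz, noise_sd = noise_sd,
            accel_coupling = accel_coupling, accel_noise_sd = accel_noise_sd,
            seed = as.integer(seed))
  validate_synth_params(p)
  class(p) <- "synth_params"
  p
}

validate_synth_params <- function(p) {
  hr <- synth_hr_profile(p, n = 2L)   # endpoints suffice for range checks
  hr_all <- if (is.numeric(p$hr_bpm) && length(p$hr_bpm) == 1L) p$hr_bpm else
    as.matrix(p$hr_bpm)[, 2L]
  if (any(hr_all < 40 | hr_all > 180)) {
    stop("hr_bpm profile must stay within [40, 180] bpm")
  }
  if (any(c(p$artifact_ratio, p$noise_sd, p$drift_amp) < 0)) {
    stop("artifact_ratio, noise_sd and drift_amp must be >= 0")
  }
  f_max <- max(length(p$pulse_shape) * max(hr_all) / 60,
               p$motion_harmonics * p$motion_freq_hz,
               p$drift_cutoff_hz)
  if (p$fs <= 2 * f_max) {
    stop(sprintf("fs = %g Hz does not satisfy fs > 2 x highest generated frequency (%g Hz)",
                 p$fs, f_max))
  }
  invisible(p)
}

# instantaneous HR (bpm) sampled on the record's time grid
synth_hr_profile <- function(p, n = NULL) {
  if (is.null(n)) n <- round(p$duration_s * p$fs)
  tt <- (seq_len(n) - 1) / p$fs
  if (is.numeric(p$hr_bpm) && length(p$hr_bpm) == 1L) {
    return(rep(p$hr_bpm, n))
  }
  prof <- as.matrix(p$hr_bpm)
  approx(prof[, 1L], prof[, 2L], xout = tt, rule = 2)$y
}

rms <- function(x) sqrt(mean(x^2))

# band-limited Gaussian drift by spectral synthesis: white noise, FFT,
# zero everything above the cutoff, inverse FFT (low-pass-filtered seeded noise)
synth_drift <- function(n, fs, cutoff_hz) {
  w <- rnorm(n)
  spec <- fft(w)
  f <- (seq_len(n) - 1) * fs / n
  keep <- f <= cutoff_hz | f >= fs - cutoff_hz   # symmetric band for real output
  keep[1L] <- FALSE                              # no DC offset
  spec[!keep] <- 0
  Re(fft(spec, inverse = TRUE)) / n
}

#' Generate a synthetic PPG + accelerometer record with ground truth
#'
#' The pulsatile component is `sum_k pulse_shape[k] * sin(2 pi k phi(t))` with
#' the phase `phi` integrating the HR profile; the motion artifact is
#' `sum_h (1/h) * sin(2 pi h f_m t + psi_h)` with random phases `psi_h`,
#' scaled so that its RMS is `artifact_ratio` times the pulsatile RMS, and
#' injected into each accelerometer axis through `accel_coupling`.
#'
#' @param params a [synth_params()] object (or arguments passed on to it).
#' @param ... used to build `params` when it is not supplied.
#' @return A list of class `synth_record_sim`: `record` (a [sensor_record()]),
#'   `clean` (noise/artifact-free PPG), `artifact`, `drift`, `hr_bpm`
#'   (instantaneous truth per sample) and `params`.
#' @examples
#' sim <- synth_record(synth_params(duration_s = 10, artifact_ratio = 0, seed = 7))
#' sim$record
#' @export
synth_record <- function(params = NULL, ...) {
  if (is.null(params)) params <- synth_params(...)
  stopifnot(inherits(params, "synth_params"))
  p <- params
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(p$seed)

  n <- round(p$duration_s * p$fs)
  tt <- (seq_len(n) - 1) / p$fs
  hr <- synth_hr_profile(p, n)
  phase <- cumsum(hr / 60) / p$fs                 # beat phase in cycles
  clean <- rep(0, n)
  for (k in seq_along(p$pulse_shape)) {
    clean <- clean + p$pulse_shape[k] * sin(2 * pi * k * phase)
  }
  prms <- rms(clean)

  drift <- rep(0, n)
  if (p$drift_amp > 0) {
    d <- synth_drift(n, p$fs, p$drift_cutoff_hz)
    if (rms(d) > 0) drift <- d * (p$drift_amp * prms / rms(d))
  }

  artifact <- rep(0, n)
  if (p$artifact_ratio > 0 && p$motion_harmonics > 0) {
    psi <- runif(p$motion_harmonics, 0, 2 * pi)
    for (h in seq_len(p$motion_harmonics)) {
      artifact <- artifact +
        (1 / h) * sin(2 * pi * h * p$motion_freq_hz * tt + psi[h])
    }
    artifact <- artifact * (p$artifact_ratio * prms / rms(artifact))
  }

  noise <- if (p$noise_sd > 0) rnorm(n, sd = p$noise_sd * prms) else rep(0, n)
  ppg <- clean + drift + artifact + noise

  accel <- sapply(p$accel_coupling, function(g) {
    ax <- g * artifact
    noise_ref <- if (rms(ax) > 0) rms(ax) else prms
    ax + rnorm(n, sd = p$accel_noise_sd * noise_ref)
  })

  rec <- sensor_record(ppg, accel, p$fs,
                       record_id = sprintf("synth-%d", p$seed))
  structure(list(record = rec, clean = clean, artifact = artifact,
                 drift = drift, hr_bpm = hr, params = p),
            class = "synth_record_sim")
}

#' Ground-truth HR per analysis window
#'
#' Mean of the instantaneous HR profile over each sliding window, matching
#' the windowing of [process_record()].
#'
#' @param sim a `synth_record_sim` from [synth_record()].
#' @param window_s window length in seconds.
#' @param hop_s hop between window starts in seconds.
#' @return Numeric vector of per-window true HR in bpm.
#' @export
window_true_hr <- function(sim, window_s = 8, hop_s = 2) {
  stopifnot(inherits(sim, "synth_record_sim"))
  fs <- sim$params$fs
  win <- round(window_s * fs)
  hop <- round(hop_s * fs)
  n <- length(sim$hr_bpm)
  starts <- seq(1L, n - win + 1L, by = hop)
  vapply(starts, function(s) mean(sim$hr_bpm[s:(s + win - 1L)]), numeric(1))
}

#' Generate a batch of synthetic records
#'
#' Draws each record's generative parameters uniformly from the given ranges,
#' with per-record seeds derived from one master seed.
#'
#' @param n number of records.
#' @param ranges named list of `c(lo, hi)` ranges for any numeric scalar
#'   [synth_params()] field (e.g. `hr_bpm`, `motion_freq_hz`,
#'   `artifact_ratio`).
#' @param seed master seed.
#' @param ... fixed [synth_params()] arguments applied to every record.
#' @return List of `synth_record_sim` objects.
#' @export
synth_batch <- function(n, ranges = list(), seed = 1L, ...) {
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, n)
  draws <- lapply(seq_len(n), function(i) {
    lapply(ranges, function(r) runif(1, r[1], r[2]))
  })
  fixed <- list(...)
  lapply(seq_len(n), function(i) {
    args <- c(draws[[i]], fixed)
    args$seed <- seeds[i]
    synth_record(do.call(synth_params, args))
  })
}
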