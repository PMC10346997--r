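# Spectral heart-rate estimation: zero-padded DFT magnitude spectrum, peak
# picking within the physiological band with temporal tracking, and an
# adaptive notch-filter artifact-removal variant for hand movement.

#' One-sided magnitude spectrum of a window
#'
#' The window is zero-meaned and zero-padded to `nfft` before the FFT; the
#' default `nfft` is the next power of two giving a grid spacing of at most
#' `resolution_bpm` (0.5 bpm), since an un-padded 8-s window would only
#' resolve 7.5 bpm.
#'
#' A Hann taper (default) is applied before the transform: the rectangular
#' window's first sidelobe (about 22% of the mainlobe) is higher than the
#' tracker's relative magnitude floor and can capture the tracked peak, while
#' Hann sidelobes are negligible.
#'
#' @param window numeric vector, non-empty.
#' @param fs sampling rate in Hz.
#' @param nfft transform length (>= `length(window)`), or `NULL` to choose
#'   from `resolution_bpm`.
#' @param resolution_bpm target frequency-grid spacing in bpm.
#' @param taper `"hann"` or `"none"`.
#' @return A list of class `hr_spectrum`: `freqs` (Hz, 0..fs/2), `mags`
#'   (magnitudes), `fs`, `nfft`.
#' @export
dft_spectrum <- function(window, fs, nfft = NULL, resolution_bpm = 0.5,
                         taper = c("hann", "none")) {
  taper <- match.arg(taper)
  if (length(window) == 0L) stop("cannot take the spectrum of an empty window")
  if (is.null(nfft)) {
    nfft <- 2^ceiling(log2(max(length(window), fs / (resolution_bpm / 60))))
  }
  if (nfft < length(window)) stop("nfft must be >= the window length")
  x <- as.numeric(window) - mean(window)
  if (taper == "hann" && length(x) > 1L) {
    n <- length(x)
    x <- x * (0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L)))
  }
  X <- fft(c(x, rep(0, nfft - length(x))))
  half <- seq_len(nfft %/% 2 + 1L)
  structure(list(freqs = (half - 1L) * fs / nfft, mags = Mod(X[half]),
                 fs = fs, nfft = nfft),
            class = "hr_spectrum")
}

# parabolic refinement of an argmax bin on a uniform grid; only refines a
# genuine local maximum (an argmax at a search-band edge is left untouched -
# there the parabola through a monotone skirt has near-zero curvature and the
# vertex lands arbitrarily far away)
parabolic_peak <- function(freqs, mags, k) {
  if (k <= 1L || k >= length(mags)) return(freqs[k])
  a <- mags[k - 1L]; b <- mags[k]; c <- mags[k + 1L]
  if (b < a || b < c) return(freqs[k])
  den <- a - 2 * b + c
  if (den >= 0) return(freqs[k])
  freqs[k] + 0.5 * (a - c) / den * (freqs[2L] - freqs[1L])
}

#' Pick the heart rate from a spectrum, with temporal tracking
#'
#' Without a previous estimate the HR is the spectral argmax within
#' `hr_band`. With one, the search is confined to
#' `prev_hr +/- max_jump_bpm`; if the best peak there is weaker than
#' `rel_floor` times the band-wide maximum the tracker concedes to the global
#' peak (`tracked = FALSE`). Ties break toward the lower frequency. If the
#' tracking band is empty after intersecting `hr_band`, the previous HR is
#' carried forward (`carried = TRUE`).
#'
#' @param spec an [dft_spectrum()] result.
#' @param hr_band heart-rate band in Hz (default 0.7-3.5 Hz, i.e. 42-210
#'   bpm).
#' @param prev_hr previous window's HR in bpm, or `NULL`.
#' When the pick is unconstrained (no previous estimate, or the tracker
#' conceded to the global peak), the selection is harmonic-aware: if the
#' spectrum also holds a peak near half the argmax frequency with at least
#' `harmonic_ratio` of its magnitude, that lower peak is taken as the pulse
#' fundamental. A PPG pulse has no sub-harmonic, so a strong peak at `f/2`
#' means `f` is the pulse's (or a residual artifact's) second harmonic, a
#' classic failure mode of plain argmax HR pickers.
#'
#' @param max_jump_bpm maximal tracked HR change per window.
#' @param rel_floor relative magnitude floor for trusting the tracked
#'   sub-band peak.
#' @param interp parabolic interpolation of the selected peak.
#' @param harmonic_ratio magnitude ratio above which the half-frequency peak
#'   is preferred over the global argmax; `0` disables the check.
#' @return A list of class `hr_estimate`: `hr_bpm`, `peak_freq_hz`,
#'   `tracked`, `carried`, `sqt` (filled by the pipeline).
#' @export
pick_hr <- function(spec, hr_band = c(0.7, 3.5), prev_hr = NULL,
                    max_jump_bpm = 10, rel_floor = 0.2, interp = TRUE,
                    harmonic_ratio = 0.5) {
  stopifnot(inherits(spec, "hr_spectrum"), length(hr_band) == 2L,
            hr_band[1] > 0, hr_band[2] > hr_band[1],
            hr_band[2] < spec$fs / 2)
  band <- which(spec$freqs >= hr_band[1] & spec$freqs <= hr_band[2])
  if (length(band) == 0L) stop("hr_band contains no frequency bins")
  finish <- function(k, tracked) {
    f <- if (interp) parabolic_peak(spec$freqs, spec$mags, k) else spec$freqs[k]
    f <- min(max(f, hr_band[1]), hr_band[2])
    structure(list(hr_bpm = 60 * f, peak_freq_hz = f, tracked = tracked,
                   carried = FALSE, sqt = NA_integer_),
              class = "hr_estimate")
  }
  subharmonic <- function(k) {
    if (harmonic_ratio <= 0) return(k)
    f_half <- spec$freqs[k] / 2
    near <- band[abs(spec$freqs[band] - f_half) <= 0.1]
    if (length(near) == 0L) return(k)
    k2 <- near[which.max(spec$mags[near])]
    if (spec$mags[k2] >= harmonic_ratio * spec$mags[k]) k2 else k
  }
  k_glob <- subharmonic(band[which.max(spec$mags[band])])
  if (is.null(prev_hr)) return(finish(k_glob, tracked = FALSE))

  sub <- band[spec$freqs[band] >= (prev_hr - max_jump_bpm) / 60 &
                spec$freqs[band] <= (prev_hr + max_jump_bpm) / 60]
  if (length(sub) == 0L) {
    return(structure(list(hr_bpm = prev_hr, peak_freq_hz = prev_hr / 60,
                          tracked = TRUE, carried = TRUE, sqt = NA_integer_),
                     class = "hr_estimate"))
  }
  k_sub <- sub[which.max(spec$mags[sub])]
  if (spec$mags[k_sub] < rel_floor * spec$mags[k_glob]) {
    return(finish(k_glob, tracked = FALSE))
  }
  finish(k_sub, tracked = TRUE)
}

#' @export
print.hr_estimate <- function(x, ...) {
  cat(sprintf("<hr_estimate> %.1f bpm (%.3f Hz)%s%s\n", x$hr_bpm,
              x$peak_freq_hz, if (x$tracked) ", tracked" else "",
              if (x$carried) ", carried forward" else ""))
  invisible(x)
}

#' Notch-filter motion-artifact removal
#'
#' Estimates the dominant motion frequency as the argmax of the summed
#' accelerometer magnitude spectra within 0.5-5 Hz and applies a zero-phase
#' second-order band-stop (notch) of bandwidth `f0 / q` at that frequency -
#' optionally also at its second harmonic. Intended for hand-movement
#' artifacts, whose cadence is narrow-band. If the accelerometer carries no
#' motion (flat or silent spectra) the PPG is returned unchanged with
#' attribute `noop = TRUE`.
#'
#' @param ppg numeric vector of PPG samples (>= 2 s).
#' @param accel n x 3 acceleration matrix.
#' @param fs sampling rate in Hz.
#' @param q notch quality factor (bandwidth = f0/q); default 5.
#' @param harmonics also notch the 2nd harmonic of the motion frequency.
#' @param motion_band frequency band searched for the cadence peak.
#' @return Filtered PPG, same length; attributes `motion_freq_hz` and `noop`.
#' @export
notch_mar <- function(ppg, accel, fs, q = 5, harmonics = FALSE,
                      motion_band = c(0.5, 5)) {
  stopifnot(q > 0)
  if (length(ppg) < 2 * fs) stop("need at least 2 s of samples for notch_mar")
  accel <- as.matrix(accel)
  stopifnot(nrow(accel) == length(ppg), ncol(accel) == 3L)

  nfft <- 2^ceiling(log2(max(length(ppg), 8 * fs)))
  mags <- rep(0, nfft %/% 2 + 1L)
  for (a in 1:3) {
    sp <- dft_spectrum(accel[, a], fs, nfft = nfft)
    mags <- mags + sp$mags
  }
  freqs <- (seq_along(mags) - 1L) * fs / nfft
  band <- which(freqs >= motion_band[1] & freqs <= motion_band[2])
  peak <- max(mags[band])
  flat <- peak <= 0 || peak < 3 * median(mags[band])
  if (flat) {
    out <- ppg
    attr(out, "noop") <- TRUE
    attr(out, "motion_freq_hz") <- NA_real_
    return(out)
  }
  f0 <- freqs[band[which.max(mags[band])]]

  out <- as.numeric(ppg)
  targets <- f0
  if (harmonics && 2 * f0 < 0.95 * fs / 2) targets <- c(f0, 2 * f0)
  for (ft in targets) {
    bw <- ft / q
    edges <- c(max(ft - bw / 2, 1e-3), min(ft + bw / 2, 0.499 * fs)) / (fs / 2)
    bs <- signal::butter(1, edges, type = "stop")     # 2nd-order band-stop
    out <- signal::filtfilt(bs, out)                  # zero-phase
  }
  attr(out, "noop") <- FALSE
  attr(out, "motion_freq_hz") <- f0
  out
}
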