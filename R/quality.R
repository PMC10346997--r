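# Signal-quality check: labels each PPG window with a binary Signal Quality
# Token (SQT). A window is qualified (SQT = 1) only if it (1) shows pulsation
# (valley count within +/-1 of peak count, enough beats), (2) has consistent
# inter-beat intervals (each consecutive difference within 10% of the
# preceding interval), and (3) has per-cycle kurtosis/mean/SD inside
# pre-defined bands on the normalized window.

#' Quality-check configuration
#'
#' @param window_s analysis window length in seconds.
#' @param hr_band plausible heart-rate band in Hz; sets the minimum peak
#'   spacing (`1/hi`) and the shortest analyzable window (`2/lo`).
#' @param tol inter-beat-interval consistency tolerance: consecutive interval
#'   differences must satisfy `|t[i+1] - t[i]| <= tol * t[i]`.
#' @param min_beats minimum number of detected peaks for a window to count as
#'   pulsatile.
#' @param prominence minimum peak prominence as a fraction of the window SD.
#' @param thresholds list of `c(lo, hi)` bands for `kurtosis`, `mean` and
#'   `std` of each cycle, evaluated on the detrended, z-normalized window.
#' @param kurtosis_convention `"pearson"` (normal = 3) or `"excess"`
#'   (normal = 0); the thresholds refer to the chosen convention.
#' @param segmentation cycle segmentation: between consecutive `"peaks"`
#'   (default) or `"valleys"`.
#' @return A list of class `quality_config`.
#' @export
quality_config <- function(window_s = 8, hr_band = c(0.7, 3.5), tol = 0.1,
                           min_beats = 3L, prominence = 0.25,
                           thresholds = list(kurtosis = c(1, 4),
                                             mean = c(-0.5, 0.5),
                                             std = c(0.3, 1.7)),
                           kurtosis_convention = c("pearson", "excess"),
                           segmentation = c("peaks", "valleys")) {
  structure(list(window_s = window_s, hr_band = hr_band, tol = tol,
                 min_beats = as.integer(min_beats), prominence = prominence,
                 thresholds = thresholds,
                 kurtosis_convention = match.arg(kurtosis_convention),
                 segmentation = match.arg(segmentation)),
            class = "quality_config")
}

# strict local maxima of x (plateau-tolerant: rising edge wins)
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

# topographic prominence of each candidate peak
peak_prominence <- function(x, peaks) {
  vapply(seq_along(peaks), function(k) {
    p <- peaks[k]; h <- x[p]
    left <- peaks[peaks < p & x[peaks] > h]
    lo_l <- if (length(left) > 0L) min(x[max(left):p]) else min(x[1:p])
    right <- peaks[peaks > p & x[peaks] > h]
    lo_r <- if (length(right) > 0L) min(x[p:min(right)]) else min(x[p:length(x)])
    h - max(lo_l, lo_r)
  }, numeric(1))
}

# greedy spacing filter: keep higher peaks first, drop any within min_dist
enforce_spacing <- function(x, peaks, min_dist) {
  if (length(peaks) <= 1L) return(peaks)
  ord <- peaks[order(x[peaks], decreasing = TRUE)]
  kept <- integer(0)
  for (p in ord) {
    if (all(abs(kept - p) >= min_dist)) kept <- c(kept, p)
  }
  sort(kept)
}

#' Detect peaks and valleys in a PPG window
#'
#' Local maxima filtered by topographic prominence (at least `prominence`
#' times the window SD) and by a minimum spacing of one period of the upper
#' heart-rate bound; valleys are detected identically on the negated signal.
#'
#' @param window numeric vector of PPG samples.
#' @param fs sampling rate in Hz.
#' @param hr_band heart-rate band in Hz, `c(lo, hi)`.
#' @param prominence minimum prominence as a fraction of the window SD.
#' @return A list of class `peak_set`: `peak_indices`, `valley_indices`
#'   (1-based sample indices) and `intervals_s` (times between consecutive
#'   peaks, seconds).
#' @export
detect_peaks_valleys <- function(window, fs, hr_band = c(0.7, 3.5),
                                 prominence = 0.25) {
  stopifnot(is.numeric(window), fs > 0, length(hr_band) == 2L,
            hr_band[1] > 0, hr_band[2] > hr_band[1])
  if (length(window) < 2 * fs / hr_band[1]) {
    stop(sprintf("window too short: need >= %.0f samples (two cycles at %.2g Hz), got %d",
                 2 * fs / hr_band[1], hr_band[1], length(window)))
  }
  min_dist <- fs / hr_band[2]
  min_prom <- prominence * sd(window)
  find <- function(x) {
    cand <- local_maxima(x)
    if (length(cand) == 0L || min_prom == 0) {
      return(if (min_prom == 0) integer(0) else cand)
    }
    cand <- cand[peak_prominence(x, cand) >= min_prom]
    enforce_spacing(x, cand, min_dist)
  }
  peaks <- find(window)
  valleys <- find(-window)
  structure(list(peak_indices = peaks, valley_indices = valleys,
                 intervals_s = if (length(peaks) > 1L) diff(peaks) / fs
                               else numeric(0)),
            class = "peak_set")
}

#' Pulsatility check
#'
#' A window is pulsatile when the valley count is within one of the peak
#' count and at least `min_beats` peaks were found.
#'
#' @param peaks a `peak_set` from [detect_peaks_valleys()].
#' @param min_beats minimum number of peaks.
#' @return `TRUE`/`FALSE`.
#' @export
check_pulsatility <- function(peaks, min_beats = 3L) {
  np <- length(peaks$peak_indices)
  nv <- length(peaks$valley_indices)
  abs(nv - np) <= 1L && np >= min_beats
}

#' Inter-beat-interval consistency check
#'
#' Every consecutive interval difference must satisfy
#' `|t[i+1] - t[i]| <= tol * t[i]`. Fewer than two intervals is insufficient
#' evidence of sustained pulsation and returns `FALSE`.
#'
#' @param intervals_s numeric vector of peak-to-peak intervals in seconds.
#' @param tol relative tolerance (default 0.1).
#' @return `TRUE`/`FALSE`.
#' @export
check_interval_consistency <- function(intervals_s, tol = 0.1) {
  n <- length(intervals_s)
  if (n < 2L) return(FALSE)
  all(abs(diff(intervals_s)) <= tol * intervals_s[-n])
}

# fourth standardized moment (population moments); normal = 3
moment_kurtosis <- function(x) {
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0) return(NaN)
  mean((x - mean(x))^4) / m2^2
}

#' Per-cycle statistics of a PPG window
#'
#' Splits the window into cycles at consecutive detected peaks (or valleys)
#' and computes kurtosis, mean and standard deviation of each cycle. The
#' caller is expected to pass a detrended, z-normalized window so the default
#' threshold bands are scale-free; [assess_quality()] does this.
#'
#' @param window numeric vector (normalized PPG samples).
#' @param peaks a `peak_set` from [detect_peaks_valleys()].
#' @param kurtosis_convention `"pearson"` (normal = 3) or `"excess"`.
#' @param segmentation `"peaks"` or `"valleys"`.
#' @return A list of class `window_stats` with numeric vectors `kurtosis`,
#'   `mean`, `std`, one entry per cycle. Degenerate (constant) cycles yield
#'   non-finite kurtosis, which fails [check_statistics()].
#' @export
window_statistics <- function(window, peaks,
                              kurtosis_convention = c("pearson", "excess"),
                              segmentation = c("peaks", "valleys")) {
  kurtosis_convention <- match.arg(kurtosis_convention)
  segmentation <- match.arg(segmentation)
  marks <- if (segmentation == "peaks") peaks$peak_indices else
    peaks$valley_indices
  if (length(marks) < 2L) stop("need at least two detected extrema (one cycle)")
  ncyc <- length(marks) - 1L
  kk <- mm <- ss <- numeric(ncyc)
  for (i in seq_len(ncyc)) {
    seg <- window[marks[i]:(marks[i + 1L] - 1L)]   # half-open cycle
    kk[i] <- moment_kurtosis(seg)
    mm[i] <- mean(seg)
    ss[i] <- sd(seg)
  }
  if (kurtosis_convention == "excess") kk <- kk - 3
  structure(list(kurtosis = kk, mean = mm, std = ss), class = "window_stats")
}

#' Statistical gating of per-cycle statistics
#'
#' `TRUE` only when every cycle's (kurtosis, mean, std) triple is finite and
#' inside all three threshold bands; an empty statistics set is rejected.
#'
#' @param stats a `window_stats` from [window_statistics()].
#' @param thresholds list with `c(lo, hi)` bands for `kurtosis`, `mean`,
#'   `std`.
#' @return `TRUE`/`FALSE`.
#' @export
check_statistics <- function(stats,
                             thresholds = quality_config()$thresholds) {
  if (length(stats$kurtosis) == 0L) return(FALSE)
  inband <- function(v, b) all(is.finite(v)) && all(v >= b[1] & v <= b[2])
  inband(stats$kurtosis, thresholds$kurtosis) &&
    inband(stats$mean, thresholds$mean) &&
    inband(stats$std, thresholds$std)
}

#' Assess the quality of one PPG window
#'
#' Runs the three checks in sequence - pulsatility, interval consistency,
#' per-cycle statistics - short-circuiting to SQT = 0 at the first failure.
#' The window is linearly detrended and z-normalized first, which makes the
#' label invariant to affine amplitude changes `c * window + d` (c > 0).
#'
#' @param window numeric vector of raw PPG samples for one window.
#' @param fs sampling rate in Hz.
#' @param config a [quality_config()].
#' @return A list of class `quality_report`: `sqt` (0/1), `pulsatility_ok`,
#'   `intervals_ok`, `stats_ok`, `peaks` (a `peak_set`), `stats`
#'   (a `window_stats` or `NULL`), `reason` (text for the first failed
#'   check, `NA` if qualified).
#' @export
assess_quality <- function(window, fs, config = quality_config()) {
  fail <- function(reason, peaks = NULL, stats = NULL,
                   p_ok = FALSE, i_ok = FALSE) {
    structure(list(sqt = 0L, pulsatility_ok = p_ok, intervals_ok = i_ok,
                   stats_ok = FALSE, peaks = peaks, stats = stats,
                   reason = reason),
              class = "quality_report")
  }
  x <- as.numeric(window)
  tt <- seq_along(x)
  trend <- stats::lm.fit(cbind(1, tt), x)$fitted.values
  x <- x - trend
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(fail("constant window"))
  x <- x / s

  peaks <- tryCatch(
    detect_peaks_valleys(x, fs, config$hr_band, config$prominence),
    error = function(e) e)
  if (inherits(peaks, "error")) return(fail(conditionMessage(peaks)))

  if (!check_pulsatility(peaks, config$min_beats)) {
    return(fail("pulsatility: peak/valley counts inconsistent or too few beats",
                peaks))
  }
  if (!check_interval_consistency(peaks$intervals_s, config$tol)) {
    return(fail("intervals: consecutive inter-beat intervals differ by > tol",
                peaks, p_ok = TRUE))
  }
  stats <- tryCatch(
    window_statistics(x, peaks, config$kurtosis_convention,
                      config$segmentation),
    error = function(e) e)
  if (inherits(stats, "error")) {
    return(fail(conditionMessage(stats), peaks, p_ok = TRUE, i_ok = TRUE))
  }
  if (!check_statistics(stats, config$thresholds)) {
    return(fail("statistics: per-cycle kurtosis/mean/std outside thresholds",
                peaks, stats, p_ok = TRUE, i_ok = TRUE))
  }
  structure(list(sqt = 1L, pulsatility_ok = TRUE, intervals_ok = TRUE,
                 stats_ok = TRUE, peaks = peaks, stats = stats,
                 reason = NA_character_),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("<quality_report> SQT = %d (pulsatility %s, intervals %s, statistics %s)\n",
              x$sqt, x$pulsatility_ok, x$intervals_ok, x$stats_ok))
  if (!is.na(x$reason)) cat("  reason:", x$reason, "\n")
  invisible(x)
}

#' Calibrate statistical thresholds from known-clean windows
#'
#' Fits each band as the `[lo_q, hi_q]` percentiles of the per-cycle
#' statistics pooled over a set of clean windows (after the same
#' detrend/z-normalize/peak-detect treatment as [assess_quality()]).
#'
#' @param windows list of numeric vectors (clean PPG windows).
#' @param fs sampling rate in Hz.
#' @param config a [quality_config()] (peak-detection settings are reused).
#' @param probs lower/upper percentiles for the bands.
#' @return A `thresholds` list usable in [quality_config()].
#' @export
calibrate_thresholds <- function(windows, fs, config = quality_config(),
                                 probs = c(0.01, 0.99)) {
  acc <- list(kurtosis = numeric(0), mean = numeric(0), std = numeric(0))
  for (w in windows) {
    x <- as.numeric(w)
    tt <- seq_along(x)
    x <- x - stats::lm.fit(cbind(1, tt), x)$fitted.values
    if (sd(x) == 0) next
    x <- x / sd(x)
    pk <- tryCatch(detect_peaks_valleys(x, fs, config$hr_band,
                                        config$prominence),
                   error = function(e) NULL)
    if (is.null(pk) || length(pk$peak_indices) < 2L) next
    st <- window_statistics(x, pk, config$kurtosis_convention,
                            config$segmentation)
    acc$kurtosis <- c(acc$kurtosis, st$kurtosis)
    acc$mean <- c(acc$mean, st$mean)
    acc$std <- c(acc$std, st$std)
  }
  if (length(acc$kurtosis) == 0L) {
    stop("no usable cycles found in the supplied windows")
  }
  lapply(acc, function(v) unname(quantile(v[is.finite(v)], probs)))
}
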