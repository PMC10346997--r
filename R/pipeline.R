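# End-to-end per-record processing: windowing, quality gating,
# motion-artifact removal (Hankel/SVD or notch path), spectral HR estimation
# with tracking, trace assembly, and agreement metrics.

#' Pipeline configuration
#'
#' Defaults follow the walking protocol: 8-s windows hopped by 2 s, a
#' 0.4-10 Hz zero-phase band-pass pre-filter, Hankel/SVD artifact removal,
#' and spectral HR tracking initialized at 78 bpm with at most a 10-bpm jump
#' between consecutive tracked windows.
#'
#' @param window_s window length in seconds.
#' @param hop_s hop between window starts in seconds (`0 < hop_s <=
#'   window_s`).
#' @param mar_method `"hankel"`, `"notch"`, or `"none"`.
#' @param bandpass pre-filter band in Hz (zero-phase Butterworth), or `NULL`
#'   to disable.
#' @param quality a [quality_config()].
#' @param hankel_mar list: `threshold`, `max_remove`, `mode` (see
#'   [select_components()]).
#' @param spectral list: `hr_band` (Hz), `resolution_bpm`, `max_jump_bpm`,
#'   `init_hr` (bpm, first-window tracking seed), `rel_floor`, `interp`,
#'   `notch_q`, `notch_harmonics`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(window_s = 8, hop_s = 2,
                            mar_method = c("hankel", "notch", "none"),
                            bandpass = c(0.4, 10),
                            quality = quality_config(window_s = window_s),
                            hankel_mar = list(threshold = 0.5,
                                              max_remove = NULL,
                                              mode = "accel_components"),
                            spectral = list(hr_band = c(0.7, 3.5),
                                            resolution_bpm = 0.5,
                                            max_jump_bpm = 10,
                                            init_hr = 78,
                                            rel_floor = 0.2,
                                            interp = TRUE,
                                            notch_q = 5,
                                            notch_harmonics = FALSE)) {
  mar_method <- match.arg(mar_method)
  if (hop_s <= 0 || hop_s > window_s) stop("need 0 < hop_s <= window_s")
  hm_def <- list(threshold = 0.5, max_remove = NULL, mode = "accel_components")
  sp_def <- list(hr_band = c(0.7, 3.5), resolution_bpm = 0.5,
                 max_jump_bpm = 10, init_hr = 78, rel_floor = 0.2,
                 interp = TRUE, notch_q = 5, notch_harmonics = FALSE)
  hankel_mar <- modifyList(hm_def, hankel_mar)
  spectral <- modifyList(sp_def, spectral)
  structure(list(window_s = window_s, hop_s = hop_s, mar_method = mar_method,
                 bandpass = bandpass, quality = quality,
                 hankel_mar = hankel_mar, spectral = spectral),
            class = "pipeline_config")
}

bandpass_filter <- function(x, fs, band) {
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  signal::filtfilt(bf, as.numeric(x))
}

#' Process a record into a heart-rate trace
#'
#' Slides a window over the record (band-pass pre-filtered at
#' `cfg$bandpass`); each window is quality-checked ([assess_quality()]) and,
#' when qualified, cleaned per `cfg$mar_method` (Hankel/SVD component
#' rejection against the accelerometer, or adaptive notch, or nothing) and
#' its HR picked from the zero-padded spectrum with temporal tracking.
#' Unqualified windows carry the previous tracked HR forward, flagged by
#' `sqt = 0` and `carried = TRUE`. The first window tracks from
#' `cfg$spectral$init_hr` (78 bpm).
#'
#' @param rec a [sensor_record()].
#' @param cfg a [pipeline_config()].
#' @return An `hr_trace`: `estimates` data frame with `window_start_s`,
#'   `window_end_s`, `hr_bpm`, `peak_freq_hz`, `sqt`, `tracked`, `carried`,
#'   plus `record_id`.
#' @examples
#' sim <- synth_record(synth_params(duration_s = 12, artifact_ratio = 0,
#'                                  noise_sd = 0.02, drift_amp = 0.1, seed = 3))
#' process_record(sim$record, pipeline_config(mar_method = "none"))
#' @export
process_record <- function(rec, cfg = pipeline_config()) {
  stopifnot(inherits(rec, "sensor_record"))
  fs <- rec$fs
  win <- round(cfg$window_s * fs)
  hop <- round(cfg$hop_s * fs)
  n <- length(rec$ppg)
  if (n < win) {
    stop(sprintf("record too short: %.2f s, need at least %g s (one window)",
                 n / fs, cfg$window_s))
  }
  ppg <- if (is.null(cfg$bandpass)) rec$ppg else
    bandpass_filter(rec$ppg, fs, cfg$bandpass)

  starts <- seq(1L, n - win + 1L, by = hop)
  sp <- cfg$spectral
  prev <- sp$init_hr
  rows <- vector("list", length(starts))
  for (w in seq_along(starts)) {
    s <- starts[w]
    idx <- s:(s + win - 1L)
    wppg <- ppg[idx]
    q <- assess_quality(wppg, fs, cfg$quality)
    if (q$sqt == 1L) {
      cleaned <- switch(cfg$mar_method,
        hankel = {
          hs <- hankel_decompose(wppg, channel_name = "ppg")
          sel <- select_components(hs, rec$accel[idx, , drop = FALSE],
                                   threshold = cfg$hankel_mar$threshold,
                                   max_remove = cfg$hankel_mar$max_remove,
                                   mode = cfg$hankel_mar$mode)
          reconstruct_series(hs, sel)
        },
        notch = notch_mar(wppg, rec$accel[idx, , drop = FALSE], fs,
                          q = sp$notch_q, harmonics = sp$notch_harmonics),
        none = wppg)
      spec <- dft_spectrum(cleaned, fs, resolution_bpm = sp$resolution_bpm)
      est <- pick_hr(spec, hr_band = sp$hr_band, prev_hr = prev,
                     max_jump_bpm = sp$max_jump_bpm,
                     rel_floor = sp$rel_floor, interp = sp$interp)
      prev <- est$hr_bpm
      rows[[w]] <- data.frame(window_start_s = (s - 1L) / fs,
                              window_end_s = (s - 1L + win) / fs,
                              hr_bpm = est$hr_bpm,
                              peak_freq_hz = est$peak_freq_hz,
                              sqt = 1L, tracked = est$tracked,
                              carried = est$carried)
    } else {
      rows[[w]] <- data.frame(window_start_s = (s - 1L) / fs,
                              window_end_s = (s - 1L + win) / fs,
                              hr_bpm = prev, peak_freq_hz = prev / 60,
                              sqt = 0L, tracked = TRUE, carried = TRUE)
    }
  }
  hr_trace(do.call(rbind, rows), record_id = rec$record_id)
}

#' Agreement metrics between an HR trace and a reference
#'
#' Mean signed error, SD of error, mean absolute error, Pearson correlation,
#' and Bland-Altman limits of agreement (mean difference +/- 1.96 SD).
#' Pearson correlation is `NA` (flagged `pearson_defined = FALSE`) when
#' either side has zero variance.
#'
#' @param trace an `hr_trace` from [process_record()], or a numeric vector of
#'   estimates in bpm.
#' @param ref numeric vector of reference HR in bpm, one per window.
#' @return A list of class `hr_metrics`: `me`, `sd`, `mae`, `pearson`,
#'   `pearson_defined`, `loa_low`, `loa_high`, `n_windows`, `n_sqt0`.
#' @examples
#' evaluate_hr(c(70, 80), c(72, 76))   # errors -2, +4: ME 1, MAE 3
#' @export
evaluate_hr <- function(trace, ref) {
  if (inherits(trace, "hr_trace")) {
    est <- trace$estimates$hr_bpm
    n_sqt0 <- sum(trace$estimates$sqt == 0L)
  } else {
    est <- as.numeric(trace)
    n_sqt0 <- 0L
  }
  ref <- as.numeric(ref)
  if (length(est) != length(ref)) {
    stop(sprintf("window count mismatch: %d estimates vs %d reference values",
                 length(est), length(ref)))
  }
  err <- est - ref
  me <- mean(err)
  sde <- if (length(err) > 1L) sd(err) else 0
  defined <- length(est) > 1L && sd(est) > 0 && sd(ref) > 0
  structure(list(me = me, sd = sde, mae = mean(abs(err)),
                 pearson = if (defined) cor(est, ref) else NA_real_,
                 pearson_defined = defined,
                 loa_low = me - 1.96 * sde, loa_high = me + 1.96 * sde,
                 n_windows = length(est), n_sqt0 = n_sqt0),
            class = "hr_metrics")
}

#' @export
print.hr_metrics <- function(x, ...) {
  cat(sprintf("<hr_metrics> n = %d windows (%d with sqt = 0)\n",
              x$n_windows, x$n_sqt0))
  cat(sprintf("  ME %.4f +/- %.4f bpm, MAE %.4f bpm\n", x$me, x$sd, x$mae))
  cat(sprintf("  Pearson r = %s; Bland-Altman LoA [%.2f, %.2f] bpm\n",
              if (x$pearson_defined) sprintf("%.4f", x$pearson) else "undefined",
              x$loa_low, x$loa_high))
  invisible(x)
}
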