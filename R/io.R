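# Sensor records and trace I/O.

#' Construct a sensor record
#'
#' A `sensor_record` bundles one PPG channel with synchronized 3-axis
#' accelerometer channels at a common sampling rate, plus an optional
#' reference heart-rate trace (one value per analysis window, e.g. from ECG
#' or an oximeter). Amplitude units are arbitrary and passed through
#' untouched; all downstream processing is amplitude-scale invariant.
#'
#' @param ppg numeric vector of PPG samples.
#' @param accel numeric matrix with `length(ppg)` rows and 3 columns
#'   (x, y, z acceleration), or a list/data.frame of three equal-length vectors.
#' @param fs sampling rate in Hz (> 0).
#' @param ref_hr optional numeric vector of reference HR values in bpm.
#' @param record_id text label for the record.
#' @return An object of class `sensor_record` with fields `ppg`, `accel`
#'   (n x 3 matrix), `fs`, `ref_hr`, `record_id`.
#' @examples
#' rec <- sensor_record(sin(2 * pi * 1.2 * (0:999) / 125),
#'                      matrix(0, 1000, 3), fs = 125)
#' rec
#' @export
sensor_record <- function(ppg, accel, fs, ref_hr = NULL, record_id = "record") {
  ppg <- as.numeric(ppg)
  if (is.data.frame(accel)) accel <- as.matrix(accel)
  if (is.list(accel)) accel <- do.call(cbind, accel)
  accel <- matrix(as.numeric(accel), ncol = 3L,
                  dimnames = list(NULL, c("ax", "ay", "az")))
  if (length(ppg) < 1L) stop("record must contain at least one sample")
  if (nrow(accel) != length(ppg)) {
    stop("accelerometer length (", nrow(accel),
         ") does not match PPG length (", length(ppg), ")")
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("fs must be a single positive number (Hz)")
  }
  bad <- which(!is.finite(ppg) | rowSums(!is.finite(accel)) > 0L)
  if (length(bad) > 0L) {
    stop("non-finite samples at indices: ",
         paste(head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) sprintf(" (and %d more)", length(bad) - 10L))
  }
  structure(list(ppg = ppg, accel = accel, fs = fs,
                 ref_hr = if (is.null(ref_hr)) NULL else as.numeric(ref_hr),
                 record_id = as.character(record_id)),
            class = "sensor_record")
}

#' @export
print.sensor_record <- function(x, ...) {
  cat(sprintf("<sensor_record '%s'>  %d samples @ %g Hz (%.1f s)\n",
              x$record_id, length(x$ppg), x$fs, length(x$ppg) / x$fs))
  if (!is.null(x$ref_hr)) {
    cat(sprintf("  reference HR: %d windows, %.0f-%.0f bpm\n",
                length(x$ref_hr), min(x$ref_hr), max(x$ref_hr)))
  }
  invisible(x)
}

# alias table: canonical name -> accepted CSV headers
csv_record_aliases <- list(
  ppg     = c("ppg", "PPG"),
  accel_x = c("accel_x", "ax", "acc_x"),
  accel_y = c("accel_y", "ay", "acc_y"),
  accel_z = c("accel_z", "az", "acc_z"),
  time    = c("time", "time_s", "t")
)

csv_find_col <- function(cols, canonical) {
  hit <- intersect(csv_record_aliases[[canonical]], cols)
  if (length(hit) == 0L) NA_character_ else hit[1L]
}

#' Read a sensor record from CSV
#'
#' Expects a header row with a PPG column and three acceleration columns
#' (`ppg`, `accel_x`/`ax`, `accel_y`/`ay`, `accel_z`/`az`), plus optionally a
#' monotonic `time` column in seconds. The sampling rate is taken from `fs`
#' when given, otherwise inferred as `1 / median(diff(time))`.
#'
#' @param path CSV file path.
#' @param fs sampling rate in Hz, or `NULL` to infer from the time column.
#' @param record_id record label; defaults to the file name.
#' @return A [sensor_record()].
#' @export
read_csv_record <- function(path, fs = NULL, record_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path)
  cols <- names(df)
  for (canonical in c("ppg", "accel_x", "accel_y", "accel_z")) {
    if (is.na(csv_find_col(cols, canonical))) {
      stop("CSV is missing required column '", canonical, "' (aliases: ",
           paste(csv_record_aliases[[canonical]], collapse = ", "), ")")
    }
  }
  tcol <- csv_find_col(cols, "time")
  if (is.null(fs)) {
    if (is.na(tcol)) stop("no fs given and no time column to infer it from")
    tt <- df[[tcol]]
    if (any(diff(tt) <= 0)) stop("time column is not strictly increasing")
    fs <- 1 / median(diff(tt))
  } else if (!is.na(tcol)) {
    tt <- df[[tcol]]
    if (any(diff(tt) <= 0)) stop("time column is not strictly increasing")
  }
  sensor_record(ppg = df[[csv_find_col(cols, "ppg")]],
                accel = cbind(df[[csv_find_col(cols, "accel_x")]],
                              df[[csv_find_col(cols, "accel_y")]],
                              df[[csv_find_col(cols, "accel_z")]]),
                fs = fs,
                record_id = if (is.null(record_id)) basename(path) else record_id)
}

#' Write a sensor record to CSV
#'
#' Columns `time,ppg,ax,ay,az`; values are written with 10 significant digits
#' so that [read_csv_record()] round-trips the record.
#'
#' @param rec a [sensor_record()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_csv_record <- function(rec, path) {
  stopifnot(inherits(rec, "sensor_record"))
  n <- length(rec$ppg)
  m <- cbind((seq_len(n) - 1) / rec$fs, rec$ppg, rec$accel)
  txt <- apply(m, 1L, function(r) paste(sprintf("%.10g", r), collapse = ","))
  writeLines(c("time,ppg,ax,ay,az", txt), path)
  invisible(path)
}

#' Read an SPC-2015-style MAT record
#'
#' The IEEE Signal Processing Cup 2015 layout: a 6-row signal matrix
#' (ECG, PPG1, PPG2, accel x/y/z) sampled at 125 Hz, with an optional
#' companion ground-truth file holding one BPM value per analysis window.
#' When `gt_path` is `NULL`, a sibling file with `DATA` replaced by `REF` in
#' its name is tried.
#'
#' @param path path to the record `.mat` file.
#' @param gt_path optional path to the ground-truth `.mat` file.
#' @param ppg_channel which PPG row to use: `"ppg1"` (default), `"ppg2"`, or
#'   `"mean"` of both.
#' @param row_map integer row indices of (ECG, PPG1, PPG2, AX, AY, AZ) in the
#'   signal matrix, for layout variants.
#' @param fs sampling rate; the dataset convention is 125 Hz.
#' @return A [sensor_record()] with `ref_hr` populated when ground truth was
#'   found.
#' @export
read_spc2015_record <- function(path, gt_path = NULL,
                                ppg_channel = c("ppg1", "ppg2", "mean"),
                                row_map = 1:6, fs = 125) {
  ppg_channel <- match.arg(ppg_channel)
  vars <- read_mat5(path)
  sig <- if ("sig" %in% names(vars)) vars[["sig"]] else {
    hit <- Filter(function(v) is.matrix(v) && nrow(v) == 6L, vars)
    if (length(hit) > 0L) hit[[1L]] else if (length(vars) > 0L) vars[[1L]] else NULL
  }
  if (is.null(sig)) stop("no signal matrix found in ", path)
  if (nrow(sig) != 6L) {
    stop("expected a signal matrix with 6 rows (ECG, PPG1, PPG2, AX, AY, AZ); got ",
         nrow(sig), " rows")
  }
  sig <- sig[row_map, , drop = FALSE]
  ppg <- switch(ppg_channel,
                ppg1 = sig[2L, ],
                ppg2 = sig[3L, ],
                mean = colMeans(sig[2:3, , drop = FALSE]))
  ref_hr <- NULL
  if (is.null(gt_path)) {
    cand <- file.path(dirname(path), sub("DATA", "REF", basename(path)))
    if (cand != path && file.exists(cand)) gt_path <- cand
  }
  if (!is.null(gt_path)) {
    gt <- read_mat5(gt_path)
    if (length(gt) > 0L) ref_hr <- as.numeric(gt[[1L]])
  }
  sensor_record(ppg = ppg, accel = t(sig[4:6, , drop = FALSE]), fs = fs,
                ref_hr = ref_hr,
                record_id = sub("\\.mat$", "", basename(path)))
}

#' Write a record in the SPC-2015 MAT layout
#'
#' Emits a 6-row `sig` matrix (ECG row zero-filled) and, when the record has
#' a reference trace, a companion ground-truth file. Mainly used to exercise
#' [read_spc2015_record()] and to export synthetic records.
#'
#' @param rec a [sensor_record()].
#' @param path output `.mat` path.
#' @param gt_path optional output path for the ground-truth file; default
#'   replaces `DATA` by `REF` in the file name when `rec$ref_hr` is present.
#' @return `path`, invisibly.
#' @export
write_spc2015_record <- function(rec, path, gt_path = NULL) {
  stopifnot(inherits(rec, "sensor_record"))
  sig <- rbind(0, rec$ppg, rec$ppg, t(rec$accel))
  write_mat5(list(sig = sig), path)
  if (!is.null(rec$ref_hr)) {
    if (is.null(gt_path)) {
      gt_path <- file.path(dirname(path), sub("DATA", "REF", basename(path)))
    }
    if (gt_path != path) write_mat5(list(BPM0 = rec$ref_hr), gt_path)
  }
  invisible(path)
}

#' Write a heart-rate trace to CSV
#'
#' @param trace an `hr_trace` as returned by [process_record()].
#' @param path output path.
#' @return `path`, invisibly.
#' @seealso [read_hr_trace()]
#' @export
write_hr_trace <- function(trace, path) {
  stopifnot(inherits(trace, "hr_trace"))
  est <- trace$estimates
  if (nrow(est) == 0L) stop("cannot write an empty HR trace")
  txt <- apply(est[, c("window_start_s", "window_end_s", "hr_bpm", "sqt")], 1L,
               function(r) paste(sprintf("%.10g", r), collapse = ","))
  writeLines(c("window_start_s,window_end_s,hr_bpm,sqt", txt), path)
  invisible(path)
}

#' Read a heart-rate trace from CSV
#'
#' @param path CSV written by [write_hr_trace()].
#' @param record_id record label.
#' @return An `hr_trace`.
#' @export
read_hr_trace <- function(path, record_id = NULL) {
  df <- read.csv(path)
  need <- c("window_start_s", "window_end_s", "hr_bpm", "sqt")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("HR trace CSV missing column(s): ", paste(miss, collapse = ", "))
  }
  hr_trace(df[need],
           record_id = if (is.null(record_id)) basename(path) else record_id)
}

hr_trace <- function(estimates, record_id = "record") {
  structure(list(estimates = as.data.frame(estimates),
                 record_id = as.character(record_id)),
            class = "hr_trace")
}

#' @export
print.hr_trace <- function(x, ...) {
  est <- x$estimates
  cat(sprintf("<hr_trace '%s'>  %d windows, %d flagged sqt=0\n",
              x$record_id, nrow(est), sum(est$sqt == 0)))
  if (nrow(est) > 0L) {
    cat(sprintf("  HR: median %.1f bpm, range %.1f-%.1f bpm\n",
                median(est$hr_bpm), min(est$hr_bpm), max(est$hr_bpm)))
  }
  invisible(x)
}

#' @export
plot.hr_trace <- function(x, ref = NULL, ...) {
  est <- x$estimates
  t_mid <- (est$window_start_s + est$window_end_s) / 2
  graphics::plot(t_mid, est$hr_bpm, type = "b", pch = ifelse(est$sqt == 1, 16, 1),
                 xlab = "time (s)", ylab = "HR (bpm)", main = x$record_id, ...)
  if (!is.null(ref)) graphics::lines(t_mid, ref, col = "red", lty = 2)
  invisible(x)
}
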