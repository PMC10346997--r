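#!/usr/bin/env Rscript
# External benchmark on the IEEE Signal Processing Cup 2015 training set
# (not distributed with the package; download it separately). Expects a
# directory of DATA_xx_TYPEyy.mat records with matching REF_xx_TYPEyy.mat
# ground-truth files, processes each record with 8-s windows hopped by 2 s,
# and reports per-record and pooled agreement metrics.
#
# Usage: Rscript scripts/spc2015_benchmark.R <data_dir> [hankel|notch|none]

suppressMessages(library(hankelppg))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1L) {
  stop("usage: Rscript scripts/spc2015_benchmark.R <data_dir> [mar_method]")
}
data_dir <- args[1L]
mar <- if (length(args) >= 2L) args[2L] else "hankel"

files <- list.files(data_dir, pattern = "^DATA.*\\.mat$", full.names = TRUE)
if (length(files) == 0L) stop("no DATA_*.mat records found in ", data_dir)

cfg <- pipeline_config(mar_method = mar)
all_est <- all_ref <- numeric(0)
for (f in files) {
  rec <- read_spc2015_record(f)
  if (is.null(rec$ref_hr)) {
    message("skipping ", basename(f), ": no REF file found")
    next
  }
  trace <- process_record(rec, cfg)
  n <- min(nrow(trace$estimates), length(rec$ref_hr))
  est <- trace$estimates$hr_bpm[seq_len(n)]
  ref <- rec$ref_hr[seq_len(n)]
  m <- evaluate_hr(est, ref)
  cat(sprintf("%-24s n=%3d  ME %7.3f +/- %7.3f  MAE %6.3f bpm\n",
              basename(f), n, m$me, m$sd, m$mae))
  all_est <- c(all_est, est)
  all_ref <- c(all_ref, ref)
}
cat("\npooled over all records:\n")
print(evaluate_hr(all_est, all_ref))
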