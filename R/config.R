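# YAML configuration round-trip for the pipeline.

config_to_list <- function(cfg) {
  list(window_s = cfg$window_s, hop_s = cfg$hop_s,
       mar_method = cfg$mar_method, bandpass = cfg$bandpass,
       quality = unclass(cfg$quality),
       hankel_mar = cfg$hankel_mar,
       spectral = cfg$spectral)
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror [pipeline_config()] (top-level `window_s`, `hop_s`,
#' `mar_method`, `bandpass`, and nested `quality:`, `hankel_mar:`,
#' `spectral:` sections); missing keys fall back to the defaults.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- pipeline_config()
  merged <- modifyList(config_to_list(base), y)
  q <- merged$quality
  thresholds <- lapply(q$thresholds, as.numeric)
  pipeline_config(
    window_s = merged$window_s, hop_s = merged$hop_s,
    mar_method = merged$mar_method,
    bandpass = if (is.null(merged$bandpass)) NULL else as.numeric(merged$bandpass),
    quality = quality_config(window_s = merged$window_s,
                             hr_band = as.numeric(q$hr_band), tol = q$tol,
                             min_beats = q$min_beats,
                             prominence = q$prominence,
                             thresholds = thresholds,
                             kurtosis_convention = q$kurtosis_convention,
                             segmentation = q$segmentation),
    hankel_mar = merged$hankel_mar,
    spectral = merged$spectral)
}

#' Write a pipeline configuration to YAML
#'
#' @param cfg a [pipeline_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  yaml::write_yaml(config_to_list(cfg), path)
  invisible(path)
}
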