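#' Analysis run configuration
#'
#' Collects every tunable of the pipeline with the field's standard defaults:
#' 0.108 um pixels, the 10 um / 0.95 nucleus QC gates, the 1 um activity
#' radius and 0.2-wide radial shells.
#'
#' @param pixel_size_um Microns per pixel (default 0.108).
#' @param mode `"simultaneous"` or `"sequential"`.
#' @param max_shift Registration search half-width in pixels; NULL = 10% of
#'   the smaller image dimension.
#' @param seg_smooth_sigma,seg_min_area_px Built-in segmenter parameters.
#' @param log_sigma LoG scale in pixels (default 2).
#' @param log_threshold Absolute LoG response threshold (default 100).
#' @param adaptive_threshold,adaptive_k Per-image adaptive thresholding
#'   (`mean + k * sd` of the response) instead of the absolute threshold.
#' @param min_diameter_um,min_circularity,drop_border Nucleus QC gates.
#' @param activity_threshold_um Active-allele DNA-RNA distance threshold in
#'   microns (default 1.0; strict `<`).
#' @param shell_width Radial shell width (default 0.2).
#' @param ks_exact_max Switchover for the exact KS p-value.
#' @param seed Seed recorded in outputs and used for any resampling.
#' @return An object of class `run_config` (a validated list).
#' @export
run_config <- function(pixel_size_um = 0.108,
                       mode = c("simultaneous", "sequential"),
                       max_shift = NULL,
                       seg_smooth_sigma = 3,
                       seg_min_area_px = 50L,
                       log_sigma = 2,
                       log_threshold = 100,
                       adaptive_threshold = FALSE,
                       adaptive_k = 5,
                       min_diameter_um = 10,
                       min_circularity = 0.95,
                       drop_border = FALSE,
                       activity_threshold_um = 1.0,
                       shell_width = 0.2,
                       ks_exact_max = 100,
                       seed = 1L) {
  mode <- match.arg(mode)
  cfg <- list(pixel_size_um = pixel_size_um, mode = mode,
              max_shift = max_shift,
              seg_smooth_sigma = seg_smooth_sigma,
              seg_min_area_px = as.integer(seg_min_area_px),
              log_sigma = log_sigma, log_threshold = log_threshold,
              adaptive_threshold = adaptive_threshold, adaptive_k = adaptive_k,
              min_diameter_um = min_diameter_um,
              min_circularity = min_circularity, drop_border = drop_border,
              activity_threshold_um = activity_threshold_um,
              shell_width = shell_width, ks_exact_max = ks_exact_max,
              seed = as.integer(seed))
  pos <- c("pixel_size_um", "seg_smooth_sigma", "log_sigma",
           "min_diameter_um", "min_circularity", "activity_threshold_um",
           "shell_width")
  for (nm in pos)
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] <= 0)
      stop(sprintf("%s must be positive", nm))
  if (cfg$log_threshold < 0) stop("log_threshold must be >= 0")
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf(paste0("<run_config %s: %.3f um/px, LoG sigma %.3g thr %.3g, ",
                     "QC >=%.3g um & >=%.3g circ, active <%.3g um, seed %d>\n"),
              x$mode, x$pixel_size_um, x$log_sigma, x$log_threshold,
              x$min_diameter_um, x$min_circularity, x$activity_threshold_um,
              x$seed))
  invisible(x)
}
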