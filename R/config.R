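# Pipeline configuration and the laterality datum.

#' Screening pipeline configuration
#'
#' Collects every tunable of the screening pipeline in one validated object.
#' The defaults materialize the published operating point: histogram stretching
#' over all `Z_k = 256` grey levels, twelve matched-filter orientations, lesion
#' binarization threshold 13 and an 80 x 80 px optic-disk removal square.
#'
#' @param median_window odd window (px) of the median denoising step.
#' @param gamma_constant multiplier of the mean-adaptive gamma attenuation
#'   (`gamma = -gamma_constant * log10(mean/255)`).
#' @param stretch_levels number of output levels of histogram stretching
#'   (`Z_k`); the full 8-bit range is 256.
#' @param mf_sigma Gaussian cross-profile scale (px) of the matched filter.
#' @param mf_length kernel length (px) along the vessel direction.
#' @param mf_orientations number of evenly spaced kernel orientations over
#'   180 degrees.
#' @param vessel_min_length minimum pixel count of a vessel component; shorter
#'   detections are pruned.
#' @param brightness_target target mean grey level of the brightness
#'   correction step in vessel extraction.
#' @param lesion_threshold fixed grey-level threshold of lesion binarization;
#'   pixels strictly above it are foreground.
#' @param variance_window odd window (px) of the diagnostic local variance map.
#' @param od_square_side side (px) of the square blanked around the detected
#'   optic-disk anchor.
#' @param od_scale if `TRUE`, `od_square_side` is rescaled proportionally to
#'   `image width / 3000` (the native width of a high-end fundus camera), so
#'   the square keeps its angular size across devices.
#' @param min_lesion_area minimum surviving foreground pixel count (and
#'   component size) for a pathological call.
#' @param laterality_side_map named list mapping laterality to the image side
#'   the optic disk is sought from (`"left"`/`"right"` edges). The default
#'   places the disk on the same side as the eye; fundus optics that mirror
#'   the image can swap it.
#' @param seed optional integer seed recorded in the config (used by phantom
#'   generation helpers; the screening path itself is deterministic).
#' @return an object of class `fs_config` (a validated named list).
#' @examples
#' cfg <- pipeline_config()
#' cfg$lesion_threshold
#' @export
pipeline_config <- function(median_window = 3L,
                            gamma_constant = 0.3,
                            stretch_levels = 256L,
                            mf_sigma = 2.0,
                            mf_length = 9L,
                            mf_orientations = 12L,
                            vessel_min_length = 50L,
                            brightness_target = 128L,
                            lesion_threshold = 13L,
                            variance_window = 5L,
                            od_square_side = 80L,
                            od_scale = FALSE,
                            min_lesion_area = 1L,
                            laterality_side_map = list(left = "left", right = "right"),
                            seed = NULL) {
  cfg <- list(
    median_window = as.integer(median_window),
    gamma_constant = as.numeric(gamma_constant),
    stretch_levels = as.integer(stretch_levels),
    mf_sigma = as.numeric(mf_sigma),
    mf_length = as.integer(mf_length),
    mf_orientations = as.integer(mf_orientations),
    vessel_min_length = as.integer(vessel_min_length),
    brightness_target = as.integer(brightness_target),
    lesion_threshold = as.integer(lesion_threshold),
    variance_window = as.integer(variance_window),
    od_square_side = as.integer(od_square_side),
    od_scale = isTRUE(od_scale),
    min_lesion_area = as.integer(min_lesion_area),
    laterality_side_map = lapply(laterality_side_map, match.arg,
                                 choices = c("left", "right")),
    seed = if (!is.null(seed)) as.integer(seed)
  )
  class(cfg) <- "fs_config"
  validate_config(cfg)
}

validate_config <- function(cfg) {
  assert_odd_window(cfg$median_window, "median_window")
  assert_odd_window(cfg$variance_window, "variance_window")
  stopifnot(
    "gamma_constant must be positive" = cfg$gamma_constant > 0,
    "stretch_levels must be >= 2" = cfg$stretch_levels >= 2L,
    "mf_sigma must be positive" = cfg$mf_sigma > 0,
    "mf_length must be >= 1" = cfg$mf_length >= 1L,
    "mf_orientations must be >= 1" = cfg$mf_orientations >= 1L,
    "vessel_min_length must be >= 1" = cfg$vessel_min_length >= 1L,
    "lesion_threshold must lie in [0, 255]" =
      cfg$lesion_threshold >= 0L && cfg$lesion_threshold <= 255L,
    "od_square_side must be >= 1" = cfg$od_square_side >= 1L,
    "min_lesion_area must be >= 1" = cfg$min_lesion_area >= 1L,
    "laterality_side_map must map left and right" =
      setequal(names(cfg$laterality_side_map), c("left", "right"))
  )
  cfg
}

#' @export
print.fs_config <- function(x, ...) {
  cat("<funduscreen pipeline configuration>\n")
  flat <- x
  flat$laterality_side_map <- sprintf("left->%s, right->%s",
                                      x$laterality_side_map$left,
                                      x$laterality_side_map$right)
  for (nm in names(flat))
    if (!is.null(flat[[nm]]))
      cat(sprintf("  %-20s %s\n", nm, paste(flat[[nm]], collapse = " ")))
  invisible(x)
}

#' Validate an eye-laterality value
#'
#' The laterality (which eye the photograph depicts) is supplied by the user
#' and determines the image side the optic disk is sought from.
#'
#' @param value `"left"` or `"right"`.
#' @return the normalized laterality string.
#' @export
laterality <- function(value) {
  match.arg(value, c("left", "right"))
}

#' Read / write a pipeline configuration as YAML
#'
#' Round-trips losslessly: `read_config(write_config(cfg, f))` reproduces the
#' config exactly.
#'
#' @param cfg an `fs_config` object.
#' @param path file path.
#' @return `write_config` returns `path` invisibly; `read_config` returns the
#'   `fs_config`.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "fs_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}
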