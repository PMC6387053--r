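# End-to-end screening driver and its result class.

#' Screen a fundus image for hard exudates
#'
#' Runs the full pipeline — preprocessing, vascular pattern extraction,
#' vessel and optic-disk removal, lesion segmentation — and returns the
#' healthy/pathological decision with the lesion mask and a blue-marked
#' overlay. Deterministic: the same image, laterality and configuration
#' always produce the same result.
#'
#' @param image `H x W x 3` RGB array (0..255) or a file path readable by
#'   [read_color_image()].
#' @param laterality `"left"` or `"right"` — which eye the photograph
#'   depicts; determines the side the optic disk is sought from.
#' @param config a [pipeline_config()].
#' @param intermediates if `TRUE`, keep every per-stage image in the result.
#' @return an object of class `retina_screen`: list with `decision`
#'   (`"healthy"`/`"pathological"`), `lesion_mask`, `lesion_pixel_count`,
#'   `lesion_component_count`, `od_anchor`, `overlay`, `vessel_mask`,
#'   `laterality`, `config` and optionally `intermediates`.
#' @examples
#' ph <- generate_phantom(phantom_spec(exudate_count = 2, seed = 7))
#' res <- screen_retina(ph$image, "right")
#' res$decision
#' @export
screen_retina <- function(image, laterality, config = pipeline_config(),
                          intermediates = FALSE) {
  if (is.character(image)) image <- read_color_image(image)
  assert_color(image)
  lat <- match.arg(laterality, c("left", "right"))
  stage <- "preprocess"
  res <- tryCatch({
    pre <- preprocess_retina(image, config, intermediates = intermediates)
    stage <- "vessels"
    vmask <- extract_vessels(image, config, intermediates = intermediates)
    stage <- "lesions"
    det <- detect_lesions(pre, vmask, lat, config, intermediates = intermediates)
    stage <- "overlay"
    det$overlay <- render_overlay(image, det$lesion_mask)
    det$vessel_mask <- vmask
    if (intermediates)
      det$intermediates <- c(det$intermediates,
                             list(preprocess = attr(pre, "intermediates"),
                                  vessels = attr(vmask, "intermediates")))
    det
  }, error = function(e) {
    stop(sprintf("screening failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  res$laterality <- lat
  res$config <- config
  class(res) <- "retina_screen"
  res
}

#' @export
print.retina_screen <- function(x, ...) {
  cat("<retina_screen>\n")
  cat("  decision:           ", x$decision, "\n")
  cat("  laterality:         ", x$laterality, "\n")
  cat("  lesion pixels:      ", x$lesion_pixel_count, "\n")
  cat("  lesion components:  ", x$lesion_component_count, "\n")
  if (!is.null(x$od_anchor))
    cat("  optic-disk anchor:  (", x$od_anchor[[1]], ",", x$od_anchor[[2]], ")\n")
  else
    cat("  optic-disk anchor:   none found\n")
  invisible(x)
}

#' @export
summary.retina_screen <- function(object, ...) {
  dims <- dim(object$lesion_mask)
  cat("Hard-exudate screening summary\n")
  cat(sprintf("  image:            %d x %d px, %s eye\n",
              dims[1], dims[2], object$laterality))
  cat(sprintf("  decision:         %s\n", object$decision))
  cat(sprintf("  lesion pixels:    %d (%.3f%% of image)\n",
              object$lesion_pixel_count,
              100 * object$lesion_pixel_count / prod(dims)))
  cat(sprintf("  lesion components:%d\n", object$lesion_component_count))
  cat(sprintf("  vessel pixels:    %d\n", sum(object$vessel_mask)))
  invisible(object)
}

#' Plot a screening result
#'
#' Displays the blue-marked overlay (and optionally the lesion and vessel
#' masks) using base graphics.
#'
#' @param x a `retina_screen` object.
#' @param which `"overlay"`, `"lesions"` or `"vessels"`.
#' @param ... unused.
#' @export
plot.retina_screen <- function(x, which = c("overlay", "lesions", "vessels"), ...) {
  which <- match.arg(which)
  img <- switch(which,
    overlay = x$overlay / 255,
    lesions = x$lesion_mask * 1,
    vessels = x$vessel_mask * 1)
  op <- graphics::par(mar = c(0.5, 0.5, 2, 0.5))
  on.exit(graphics::par(op))
  graphics::plot.new()
  graphics::plot.window(c(0, 1), c(0, 1), asp = dim(x$lesion_mask)[1] /
                          dim(x$lesion_mask)[2])
  graphics::rasterImage(img, 0, 0, 1, 1)
  graphics::title(sprintf("%s (%s)", which, x$decision))
  invisible(x)
}

#' Save screening artifacts to disk
#'
#' Writes `lesions.png` (mask), `overlay.png`, optionally `variance.png` and
#' the per-stage intermediates, plus a one-line JSON verdict (`verdict.json`
#' with `decision`, `lesion_pixel_count`, `od_anchor`).
#'
#' @param result a `retina_screen` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_screening <- function(result, dir) {
  stopifnot(inherits(result, "retina_screen"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_mask(result$lesion_mask, file.path(dir, "lesions.png"))
  write_color_image(result$overlay, file.path(dir, "overlay.png"))
  write_mask(result$vessel_mask, file.path(dir, "vessels.png"))
  if (!is.null(result$intermediates)) {
    if (!is.null(result$intermediates$variance))
      write_gray_image(result$intermediates$variance,
                       file.path(dir, "variance.png"))
    pp <- result$intermediates$preprocess
    if (!is.null(pp)) {
      write_gray_image(pp$green, file.path(dir, "01_green.png"))
      write_gray_image(pp$stretched, file.path(dir, "02_stretched.png"))
      write_gray_image(pp$median, file.path(dir, "03_median.png"))
      write_gray_image(pp$gamma, file.path(dir, "04_gamma.png"))
    }
  }
  verdict <- list(decision = result$decision,
                  lesion_pixel_count = result$lesion_pixel_count,
                  od_anchor = if (!is.null(result$od_anchor))
                    as.integer(result$od_anchor))
  jsonlite::write_json(verdict, file.path(dir, "verdict.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(dir)
}
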