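# Stage 3: vessel removal, lesion segmentation, optic-disk removal and the
# healthy/pathological decision.

#' Black out vessel pixels
#'
#' Sets every pixel under the vessel mask to 0 (vessels cannot carry hard
#' exudates, so their pixels are excluded before lesion thresholding). All
#' other pixels are unchanged.
#'
#' @param image grey matrix.
#' @param vessel_mask logical matrix of the same shape.
#' @return grey matrix with vessel pixels at 0.
#' @export
mask_out_vessels <- function(image, vessel_mask) {
  assert_gray(image)
  assert_mask(vessel_mask, "vessel_mask")
  if (!identical(dim(image), dim(vessel_mask)))
    stop("image and vessel mask shapes differ", call. = FALSE)
  image[vessel_mask] <- 0L
  image
}

#' Fixed-threshold binarization
#'
#' Foreground is every pixel strictly above the threshold. The default 13 is
#' the pipeline's published lesion operating point: after the mean-adaptive
#' gamma attenuation only the optic disk and bright lesions exceed it.
#'
#' @param image grey matrix.
#' @param threshold grey level in 0..255 (default 13).
#' @return logical mask, TRUE where `image > threshold`.
#' @export
binarize_fixed <- function(image, threshold = 13L) {
  assert_gray(image)
  stopifnot("threshold must lie in [0, 255]" = threshold >= 0 && threshold <= 255)
  image > threshold
}

#' Local variance map of a binary mask
#'
#' Per-pixel population variance of the 0/1 mask over a `window x window`
#' neighbourhood (replicate borders), rescaled so the maximum attainable
#' binary variance 0.25 maps to 255. Highlights the boundaries of segmented
#' structures; exposed as a diagnostic.
#'
#' @param mask logical matrix.
#' @param window odd window size (default 5).
#' @return grey matrix, values 0..255.
#' @export
local_variance_map <- function(mask, window = 5L) {
  assert_mask(mask)
  w <- assert_odd_window(window)
  m <- mask * 1.0
  p <- box_mean(m, w)
  p2 <- box_mean(m * m, w)
  v <- pmax(p2 - p * p, 0)
  out <- round_half_up(v / 0.25 * 255)
  storage.mode(out) <- "integer"
  out
}

#' Locate the optic-disk anchor
#'
#' Scans the binarized image column by column starting from the image edge
#' implied by the eye's laterality (default: right eye from the rightmost
#' column inward, left eye from the leftmost), top to bottom within each
#' column, and returns the first foreground pixel. The optic disk is the
#' brightest normal structure and, in a fundus photograph, sits on the
#' laterality side, so this pixel anchors its removal.
#'
#' @param mask logical matrix (binarized lesion candidates).
#' @param laterality `"left"` or `"right"`.
#' @param side_map named list mapping laterality to a scan edge (see
#'   [pipeline_config()]).
#' @return `c(row, col)` of the anchor, or `NULL` if the mask is empty.
#' @export
locate_optic_disk_anchor <- function(mask, laterality,
                                     side_map = list(left = "left", right = "right")) {
  assert_mask(mask)
  lat <- match.arg(laterality, c("left", "right"))
  side <- match.arg(side_map[[lat]], c("left", "right"))
  hit <- which(mask, arr.ind = TRUE)
  if (nrow(hit) == 0L) return(NULL)
  col <- if (side == "right") max(hit[, 2]) else min(hit[, 2])
  row <- min(hit[hit[, 2] == col, 1])
  c(row = row, col = col)
}

#' Blank a square around the optic-disk anchor
#'
#' Sets to background all pixels of the `side x side` axis-aligned square
#' centred on the anchor, clipped at the image borders. With the default
#' side of 80 px the square covers the optic disk found by
#' [locate_optic_disk_anchor()]. Never adds foreground.
#'
#' @param mask logical matrix.
#' @param anchor `c(row, col)`, or `NULL` (mask returned unchanged with a
#'   message).
#' @param side square side in px (default 80).
#' @return mask with the square blanked.
#' @export
remove_optic_disk <- function(mask, anchor, side = 80L) {
  assert_mask(mask)
  stopifnot("side must be >= 1" = side >= 1)
  if (is.null(anchor)) {
    message("no optic-disk anchor found; mask left unchanged")
    return(mask)
  }
  r <- anchor[[1]]; cl <- anchor[[2]]
  if (r < 1 || r > nrow(mask) || cl < 1 || cl > ncol(mask))
    stop("anchor lies outside the image", call. = FALSE)
  half_lo <- ceiling(side / 2) - 1L   # 39 for side 80
  half_hi <- floor(side / 2)          # 40 for side 80
  rows <- max(1L, r - half_lo):min(nrow(mask), r + half_hi)
  cols <- max(1L, cl - half_lo):min(ncol(mask), cl + half_hi)
  mask[rows, cols] <- FALSE
  mask
}

#' Healthy/pathological decision from the lesion mask
#'
#' Components smaller than `min_lesion_area` pixels are discarded; the retina
#' is called pathological iff the surviving foreground pixel count is at
#' least `min_lesion_area`. The default of 1 reproduces the strictest rule:
#' any residual bright pixel is a pathological call. Monotone: adding
#' foreground can never flip pathological to healthy.
#'
#' @param mask logical lesion mask.
#' @param min_lesion_area minimum component/total pixel count (default 1).
#' @return `"pathological"` or `"healthy"`.
#' @export
classify_retina <- function(mask, min_lesion_area = 1L) {
  assert_mask(mask)
  stopifnot("min_lesion_area must be >= 1" = min_lesion_area >= 1)
  surviving <- remove_small_components(mask, min_lesion_area)
  if (sum(surviving) >= min_lesion_area) "pathological" else "healthy"
}

#' Overlay lesions on the colour image
#'
#' Marks every lesion pixel in pure blue (0, 0, 255) on a copy of the input;
#' all other pixels are untouched. Blue pixels in the overlay correspond
#' exactly to the mask support.
#'
#' @param image `H x W x 3` RGB array.
#' @param mask logical matrix of the same height/width.
#' @return RGB array with lesions painted blue.
#' @export
render_overlay <- function(image, mask) {
  assert_color(image)
  assert_mask(mask)
  if (!identical(dim(image)[1:2], dim(mask)))
    stop("image and mask shapes differ", call. = FALSE)
  out <- image
  r <- out[, , 1]; g <- out[, , 2]; b <- out[, , 3]
  r[mask] <- 0L; g[mask] <- 0L; b[mask] <- 255L
  out[, , 1] <- r; out[, , 2] <- g; out[, , 3] <- b
  out
}

#' Lesion detection and classification
#'
#' Stage-3 composition on the preprocessed image: vessel removal -> fixed
#' threshold binarization -> (diagnostic) local variance map -> optic-disk
#' anchor search on the binarized mask -> optic-disk square removal ->
#' healthy/pathological decision.
#'
#' @param preprocessed stage-1 output grey matrix.
#' @param vessel_mask stage-2 vessel mask.
#' @param laterality `"left"` or `"right"`.
#' @param config a [pipeline_config()].
#' @param intermediates if `TRUE`, keep per-stage artifacts in the result.
#' @return list with `decision`, `lesion_mask`, `lesion_pixel_count`,
#'   `lesion_component_count`, `od_anchor` and (optionally) `intermediates`.
#' @export
detect_lesions <- function(preprocessed, vessel_mask, laterality,
                           config = pipeline_config(), intermediates = FALSE) {
  assert_gray(preprocessed)
  lat <- match.arg(laterality, c("left", "right"))
  devesseled <- mask_out_vessels(preprocessed, vessel_mask)
  candidates <- binarize_fixed(devesseled, config$lesion_threshold)
  variance <- local_variance_map(candidates, config$variance_window)
  anchor <- locate_optic_disk_anchor(candidates, lat, config$laterality_side_map)
  side <- config$od_square_side
  if (config$od_scale)
    side <- max(1L, as.integer(round_half_up(side * ncol(preprocessed) / 3000)))
  lesions <- remove_optic_disk(candidates, anchor, side)
  decision <- classify_retina(lesions, config$min_lesion_area)
  surviving <- remove_small_components(lesions, config$min_lesion_area)
  n_comp <- if (any(surviving)) max(label_components(surviving)) else 0L
  res <- list(decision = decision,
              lesion_mask = surviving,
              lesion_pixel_count = sum(surviving),
              lesion_component_count = n_comp,
              od_anchor = anchor)
  if (intermediates)
    res$intermediates <- list(devesseled = devesseled, binarized = candidates,
                              variance = variance)
  res
}
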