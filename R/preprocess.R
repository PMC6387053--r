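# Stage 1: image preprocessing.
#
# Green-channel conversion, full-range histogram stretching, median denoising
# and a mean-adaptive gamma attenuation. The output feeds both the vessel
# extractor (which re-enhances its own copy) and, after vessel removal, the
# lesion segmentation.

#' Green-channel grayscale conversion
#'
#' Retinal structure contrast (vessels, exudates) is strongest in the green
#' channel of a fundus photograph, which is therefore used as the grayscale
#' representation throughout the pipeline.
#'
#' @param image `H x W x 3` RGB array, values 0..255.
#' @return grey matrix equal to the green channel, bit-exact.
#' @export
to_green_gray <- function(image) {
  assert_color(image)
  g <- image[, , 2, drop = FALSE]
  dim(g) <- dim(image)[1:2]
  storage.mode(g) <- "integer"
  g
}

#' Full-range histogram stretching
#'
#' Affine remap of grey levels so the observed minimum maps to 0 and the
#' observed maximum to `levels - 1` (255 for the full 8-bit range):
#' `S' = round((S - k_min) / (k_max - k_min) * (Z_k - 1))`. Rank order of
#' pixel values is preserved and the map is idempotent after the first
#' application.
#'
#' A constant image has no contrast to stretch; it is returned as all zeros
#' with a warning.
#'
#' @param image grey matrix.
#' @param levels number of output levels `Z_k` (default 256, i.e. output span
#'   0..255).
#' @return stretched grey matrix.
#' @export
stretch_histogram <- function(image, levels = 256L) {
  assert_gray(image)
  stopifnot("levels must be >= 2" = levels >= 2)
  k_min <- min(image)
  k_max <- max(image)
  if (k_max == k_min) {
    warning("constant image: histogram stretching is degenerate, returning zeros")
    return(matrix(0L, nrow(image), ncol(image)))
  }
  out <- round_half_up((image - k_min) / (k_max - k_min) * (levels - 1))
  storage.mode(out) <- "integer"
  out
}

#' Median denoising
#'
#' Classic median filter: each output pixel is the median of its
#' `window x window` neighbourhood, with replicate padding at the borders.
#' Exact for 8-bit data.
#'
#' @param image grey matrix, values 0..255.
#' @param window odd window size in px.
#' @return filtered grey matrix.
#' @export
median_denoise <- function(image, window = 3L) {
  assert_gray(image)
  w <- assert_odd_window(window)
  if (w == 1L) return(image)
  k <- (w - 1L) %/% 2L
  p <- pad_replicate(image, k)
  f <- EBImage::medianFilter(p / 255, k) * 255
  out <- round_half_up(as.matrix(f)[(k + 1):(k + nrow(image)),
                                    (k + 1):(k + ncol(image)), drop = FALSE])
  storage.mode(out) <- "integer"
  out
}

#' Mean-adaptive gamma coefficient
#'
#' Computes `gamma = -c * log10(X)` where `X` is the image mean normalized to
#' `(0, 1]`. Bright images (large `X`) get a small gamma, dark images a larger
#' one, so the subsequent attenuation (see [gamma_correct()]) equalizes global
#' brightness across acquisitions. The coefficient is clamped to
#' `[0.02, 10]`; the lower clamp fires in the singular limit `X -> 1`
#' (`log10(1) = 0`).
#'
#' @param image grey matrix, not all zero.
#' @param gamma_constant the constant `c` (default 0.3).
#' @return list with `mean_intensity` (the normalized mean `X`) and `gamma`.
#' @examples
#' img <- matrix(25.5, 10, 10)  # normalized mean 0.1
#' compute_gamma(img)$gamma     # 0.3
#' @export
compute_gamma <- function(image, gamma_constant = 0.3) {
  assert_gray(image)
  stopifnot("gamma_constant must be positive" = gamma_constant > 0)
  x <- mean(image) / 255
  if (x <= 0)
    stop("all-zero image: mean intensity is 0, gamma is undefined", call. = FALSE)
  g <- -gamma_constant * log10(x)
  if (g < 0.02 || g > 10) {
    warning(sprintf("gamma %.4g outside [0.02, 10]; clamped", g))
    g <- min(max(g, 0.02), 10)
  }
  list(mean_intensity = x, gamma = g)
}

#' Gamma attenuation
#'
#' Multiplies every pixel by the gamma coefficient and rounds:
#' `out = round(gamma * in)`, clipped to 0..255. With the mean-adaptive
#' coefficient of [compute_gamma()] this darkens the retinal background to
#' near black while the optic disk and bright lesions remain above the
#' downstream fixed binarization threshold — the brightness-unifying step
#' that makes a single global threshold usable across images.
#'
#' Monotone non-decreasing in pixel value; 0 always maps to 0.
#'
#' @param image grey matrix.
#' @param params list with element `gamma` (as returned by [compute_gamma()]),
#'   or a single number.
#' @return attenuated grey matrix.
#' @export
gamma_correct <- function(image, params) {
  assert_gray(image)
  g <- if (is.list(params)) params$gamma else params
  stopifnot("gamma must be a positive number" = is.numeric(g) && g > 0)
  out <- clip8(round_half_up(g * image))
  storage.mode(out) <- "integer"
  out
}

#' Stage-1 preprocessing pipeline
#'
#' Composition, in order: green channel -> histogram stretching -> median
#' denoising -> mean-adaptive gamma attenuation.
#'
#' @param image `H x W x 3` RGB array.
#' @param config a [pipeline_config()].
#' @param intermediates if `TRUE`, attach the per-stage images as an attribute
#'   `"intermediates"` (named list `green`, `stretched`, `median`, `gamma`).
#' @return preprocessed grey matrix.
#' @export
preprocess_retina <- function(image, config = pipeline_config(),
                              intermediates = FALSE) {
  assert_color(image)
  green <- to_green_gray(image)
  stretched <- stretch_histogram(green, config$stretch_levels)
  denoised <- median_denoise(stretched, config$median_window)
  if (all(denoised == 0L)) {
    # constant-colour input collapses to zeros at the stretch stage
    out <- denoised
    gp <- list(mean_intensity = 0, gamma = NA_real_)
  } else {
    gp <- compute_gamma(denoised, config$gamma_constant)
    out <- gamma_correct(denoised, gp)
  }
  if (intermediates)
    attr(out, "intermediates") <- list(green = green, stretched = stretched,
                                       median = denoised, gamma = out,
                                       gamma_params = gp)
  out
}
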