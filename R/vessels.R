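# Stage 2: retinal vascular pattern extraction.
#
# Vessels are curvilinear structures, locally darker than the background in
# the green channel. They are enhanced (equalization + brightness
# normalization), detected with a bank of oriented zero-mean Gaussian matched
# filters, binarized at the maximum-entropy threshold and pruned of short
# spurious components.

#' Global histogram equalization
#'
#' CDF-based equalization on 256 bins with the conventional rescaling by the
#' lowest occupied bin: `out = round(255 * (cdf(v) - cdf_min) / (1 - cdf_min))`.
#' Rank order is preserved up to ties; a constant image is returned unchanged.
#'
#' @param image grey matrix, values 0..255.
#' @return equalized grey matrix.
#' @export
equalize_histogram <- function(image) {
  assert_gray(image)
  h <- tabulate(image + 1L, nbins = 256L)
  cdf <- cumsum(h) / length(image)
  cdf_min <- cdf[which(h > 0)[1]]
  if (cdf_min == 1) return(image)  # constant image
  map <- round_half_up(255 * (cdf - cdf_min) / (1 - cdf_min))
  out <- matrix(as.integer(map[image + 1L]), nrow(image), ncol(image))
  out
}

#' Multiplicative brightness correction
#'
#' Applies the gain `target_mean / mean(image)` and clips to 0..255, bringing
#' the global mean to the target unless clipping saturates.
#'
#' @param image grey matrix, not all zero.
#' @param target_mean target mean grey level (default 128).
#' @return corrected grey matrix.
#' @export
brightness_correct <- function(image, target_mean = 128) {
  assert_gray(image)
  m <- mean(image)
  if (m == 0)
    stop("all-zero image: brightness correction is undefined", call. = FALSE)
  out <- clip8(round_half_up(image * (target_mean / m)))
  storage.mode(out) <- "integer"
  out
}

#' Oriented Gaussian matched-filter bank
#'
#' Builds `n_orientations` rotated copies of the classic vessel-matched
#' kernel: a negated Gaussian cross-profile `-exp(-u^2 / (2 sigma^2))` swept
#' along a straight segment of the given length, sampled on a square support
#' wide enough to hold every rotation, then mean-subtracted so each kernel
#' sums to zero. Orientations are `i * 180 / n` degrees, `i = 0 .. n-1`
#' (a kernel is invariant under a 180-degree turn). The sign convention makes
#' locally dark linear structures on a brighter background respond positively.
#'
#' @param sigma Gaussian scale of the cross profile, px.
#' @param length segment length `L`, px; the profile is kept for `|v| <= L/2`.
#' @param n_orientations number of orientations over 180 degrees (default 12,
#'   i.e. 15-degree steps).
#' @return object of class `fs_filter_bank`: list with `kernels` (list of
#'   square zero-sum matrices), `orientations` (degrees), `sigma`, `length`.
#' @export
matched_filter_bank <- function(sigma = 2.0, length = 9L, n_orientations = 12L) {
  stopifnot("sigma must be positive" = sigma > 0,
            "length must be >= 1" = length >= 1,
            "n_orientations must be >= 1" = n_orientations >= 1)
  s <- ceiling(sqrt((3 * sigma)^2 + (length / 2)^2))
  off <- seq(-s, s)
  cc <- matrix(off, 2 * s + 1, 2 * s + 1, byrow = TRUE)  # col offsets
  rr <- matrix(off, 2 * s + 1, 2 * s + 1)                # row offsets
  angles <- (seq_len(n_orientations) - 1) * 180 / n_orientations
  kernels <- lapply(angles, function(theta) {
    t <- theta * pi / 180
    u <- cc * cos(t) + rr * sin(t)   # across the vessel
    v <- -cc * sin(t) + rr * cos(t)  # along the vessel
    sup <- abs(u) <= 3 * sigma & abs(v) <= length / 2
    k <- matrix(0, 2 * s + 1, 2 * s + 1)
    k[sup] <- -exp(-u[sup]^2 / (2 * sigma^2))
    k[sup] <- k[sup] - mean(k[sup])
    k
  })
  structure(list(kernels = kernels, orientations = angles,
                 sigma = sigma, length = length),
            class = "fs_filter_bank")
}

#' Maximum matched-filter response
#'
#' Correlates the image with every kernel of the bank (replicate borders) and
#' keeps the per-pixel maximum over orientations. Because each kernel sums to
#' zero, the response is invariant to adding a constant to the image and is
#' identically zero on constant images.
#'
#' @param image grey matrix.
#' @param bank an [matched_filter_bank()] object.
#' @return real-valued response matrix, same shape as `image`.
#' @export
matched_filter_response <- function(image, bank) {
  assert_gray(image)
  stopifnot(inherits(bank, "fs_filter_bank"))
  img <- image * 1.0
  resp <- NULL
  for (k in bank$kernels) {
    r <- as.matrix(EBImage::filter2(img, k, boundary = "replicate"))
    resp <- if (is.null(resp)) r else pmax(resp, r)
  }
  resp
}

#' Maximum-entropy (Kapur) threshold
#'
#' Linearly quantizes the response to 256 bins and exhaustively scans all
#' split points for the one maximizing the summed Shannon entropies of the
#' background and foreground grey-level distributions. Ties resolve to the
#' lowest split.
#'
#' @param response real matrix with at least two distinct values.
#' @return the threshold on the response scale; pixels strictly above it are
#'   foreground.
#' @export
entropy_threshold <- function(response) {
  if (!is.matrix(response) || !is.numeric(response))
    stop("`response` must be a numeric matrix", call. = FALSE)
  lo <- min(response); hi <- max(response)
  if (!is.finite(lo) || !is.finite(hi))
    stop("response contains non-finite values", call. = FALSE)
  if (hi == lo)
    stop("constant response: entropy threshold is undefined", call. = FALSE)
  bins <- round_half_up((response - lo) / (hi - lo) * 255)
  p <- tabulate(bins + 1L, nbins = 256L) / length(bins)
  plogp <- ifelse(p > 0, p * log(p), 0)
  omega <- cumsum(p)
  H <- cumsum(-plogp)
  H_tot <- H[256]
  t_all <- 1:255                      # split after bin t-1 (0-based t = 0..254)
  ok <- omega[t_all] > 0 & omega[t_all] < 1
  psi <- rep(-Inf, 255)
  w <- omega[t_all][ok]; h <- H[t_all][ok]
  psi[ok] <- log(w * (1 - w)) + h / w + (H_tot - h) / (1 - w)
  t_best <- which.max(psi) - 1L       # 0-based bin index
  lo + (t_best + 0.5) * (hi - lo) / 255
}

#' Prune small binary components
#'
#' Removes 8-connected components with fewer than `min_length` pixels;
#' larger components are untouched. Idempotent, and monotone in `min_length`.
#'
#' @param mask logical matrix.
#' @param min_length minimum component pixel count to keep.
#' @return pruned logical matrix.
#' @export
remove_small_components <- function(mask, min_length = 50L) {
  assert_mask(mask)
  stopifnot("min_length must be >= 1" = min_length >= 1)
  if (min_length == 1L || !any(mask)) return(mask)
  lab <- label_components(mask)
  sizes <- component_sizes(lab)
  keep <- which(sizes >= min_length)
  matrix(lab %in% keep, nrow(mask), ncol(mask)) & mask
}

#' Extract the retinal vascular pattern
#'
#' Full stage-2 composition: green channel -> median denoising -> histogram
#' equalization -> brightness correction -> oriented matched filtering ->
#' maximum-entropy binarization -> short-component pruning.
#'
#' @param image `H x W x 3` RGB array.
#' @param config a [pipeline_config()].
#' @param intermediates if `TRUE`, attach per-stage images as attribute
#'   `"intermediates"`.
#' @return logical vessel mask (TRUE = vessel).
#' @export
extract_vessels <- function(image, config = pipeline_config(),
                            intermediates = FALSE) {
  assert_color(image)
  green <- to_green_gray(image)
  denoised <- median_denoise(green, config$median_window)
  equalized <- equalize_histogram(denoised)
  if (min(equalized) == max(equalized)) {
    # constant image: no vascular structure to extract
    empty <- matrix(FALSE, nrow(equalized), ncol(equalized))
    if (intermediates)
      attr(empty, "intermediates") <- list(green = green, median = denoised,
                                           equalized = equalized)
    return(empty)
  }
  corrected <- brightness_correct(equalized, config$brightness_target)
  bank <- matched_filter_bank(config$mf_sigma, config$mf_length,
                              config$mf_orientations)
  response <- matched_filter_response(corrected, bank)
  thr <- entropy_threshold(response)
  raw_mask <- response > thr
  mask <- remove_small_components(raw_mask, config$vessel_min_length)
  if (intermediates)
    attr(mask, "intermediates") <- list(
      green = green, median = denoised, equalized = equalized,
      brightness = corrected, response = response, threshold = thr,
      raw_mask = raw_mask)
  mask
}
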