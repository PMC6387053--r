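# Image input/output. Internal representation is fixed: 8-bit RGB arrays
# (H x W x 3, values 0..255, channel order RGB regardless of container),
# grey matrices (H x W) and logical masks. Row-major display convention:
# [row, col], origin at the top-left.

#' Read a colour fundus image
#'
#' Decodes PNG, JPEG or TIFF into an 8-bit `H x W x 3` RGB array. Alpha
#' channels are dropped; channel order is always RGB.
#'
#' @param path path to a `.png`, `.jpg`/`.jpeg` or `.tif`/`.tiff` file.
#' @return integer array `H x W x 3` with values in 0..255.
#' @export
read_color_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: no such file: ", path,
                               call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png  = try(png::readPNG(path), silent = TRUE),
    jpg  = ,
    jpeg = try(jpeg::readJPEG(path), silent = TRUE),
    tif  = ,
    tiff = try(tiff::readTIFF(path), silent = TRUE),
    stop("unsupported image format: .", ext, call. = FALSE))
  if (inherits(raw, "try-error"))
    stop("failed to decode image file: ", path, call. = FALSE)
  if (length(dim(raw)) != 3L || dim(raw)[3] < 3L)
    stop("image is not a 3-channel colour raster (the pipeline requires ",
         "RGB input to extract the green channel): ", path, call. = FALSE)
  out <- round_half_up(raw[, , 1:3, drop = FALSE] * 255)
  storage.mode(out) <- "integer"
  out
}

#' Write a colour image as PNG
#'
#' @param image `H x W x 3` array, values 0..255.
#' @param path output path (PNG).
#' @return `path`, invisibly.
#' @export
write_color_image <- function(image, path) {
  assert_color(image)
  png::writePNG(clip8(image) / 255, path)
  invisible(path)
}

#' Read / write a binary mask as PNG
#'
#' Masks are written with foreground = 255, background = 0; on reading, any
#' pixel above half-scale counts as foreground.
#'
#' @param mask logical matrix.
#' @param path file path (PNG).
#' @return `write_mask` returns `path` invisibly; `read_mask` a logical matrix.
#' @export
write_mask <- function(mask, path) {
  assert_mask(mask)
  png::writePNG(mask * 1, path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  raw <- png::readPNG(path)
  if (length(dim(raw)) == 3L) raw <- raw[, , 1]
  raw > 0.5
}

#' Write a grey image as PNG
#'
#' @param image grey matrix, values 0..255.
#' @param path file path (PNG).
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(image, path) {
  assert_gray(image)
  png::writePNG(clip8(image) / 255, path)
  invisible(path)
}
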