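# Shared low-level helpers: 8-bit arithmetic, padding, connected components.

#' Round half away from zero
#'
#' Grey levels are produced with commercial rounding (0.5 rounds up), not
#' banker's rounding, so that integer results are stable across platforms.
#'
#' @param x numeric vector or matrix.
#' @return `x` rounded to the nearest integer, halves up.
#' @keywords internal
round_half_up <- function(x) floor(x + 0.5)

# Clamp to the 8-bit grey range.
clip8 <- function(x) pmin(pmax(x, 0), 255)

#' @keywords internal
is_gray_image <- function(x) is.matrix(x) && is.numeric(x)

#' @keywords internal
is_color_image <- function(x) is.array(x) && length(dim(x)) == 3L && dim(x)[3] == 3L

assert_gray <- function(image, arg = "image") {
  if (!is_gray_image(image))
    stop(sprintf("`%s` must be a numeric H x W matrix of grey levels", arg),
         call. = FALSE)
  if (length(image) == 0L)
    stop(sprintf("`%s` is empty", arg), call. = FALSE)
  invisible(image)
}

assert_color <- function(image, arg = "image") {
  if (!is_color_image(image))
    stop(sprintf("`%s` must be an H x W x 3 RGB array", arg), call. = FALSE)
  invisible(image)
}

assert_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask) || !is.logical(mask))
    stop(sprintf("`%s` must be a logical H x W matrix", arg), call. = FALSE)
  invisible(mask)
}

assert_odd_window <- function(window, arg = "window") {
  if (length(window) != 1L || !is.finite(window) || window < 1 || window %% 2 != 1)
    stop(sprintf("`%s` must be an odd integer >= 1 (got %s)", arg,
                 paste(window, collapse = ",")), call. = FALSE)
  invisible(as.integer(window))
}

#' Replicate-pad a matrix
#'
#' Extends a matrix by `k` rows/columns on every side by repeating the edge
#' values; this is the border policy of every windowed operation in the
#' pipeline.
#'
#' @param m matrix.
#' @param k non-negative integer pad width.
#' @return the padded matrix, dimensions `dim(m) + 2k`.
#' @keywords internal
pad_replicate <- function(m, k) {
  if (k == 0L) return(m)
  r <- nrow(m); cl <- ncol(m)
  m[c(rep(1L, k), seq_len(r), rep(r, k)),
    c(rep(1L, k), seq_len(cl), rep(cl, k)), drop = FALSE]
}

#' Label 8-connected components of a binary mask
#'
#' Pixels are connected if they touch by edge or corner. Implemented as graph
#' components over the 8-neighbour pixel lattice restricted to the foreground.
#'
#' @param mask logical matrix.
#' @return integer matrix of the same shape; 0 = background, components
#'   numbered from 1.
#' @export
label_components <- function(mask) {
  assert_mask(mask)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  fg <- which(mask)
  if (length(fg) == 0L) return(lab)
  nr <- nrow(mask)
  id <- match(seq_len(length(mask)), fg)      # linear index -> vertex id
  # Edges to S, E, SE, NE neighbours (the other four are their mirrors).
  row <- (fg - 1L) %% nr + 1L
  col <- (fg - 1L) %/% nr + 1L
  edges <- integer(0)
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- row + off[1]; c2 <- col + off[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= ncol(mask)
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    keep <- !is.na(id[nb]) & mask[nb]
    if (any(keep))
      edges <- c(edges, rbind(id[fg[ok][keep]], id[nb[keep]]))
  }
  g <- igraph::make_graph(edges = edges, n = length(fg), directed = FALSE)
  comp <- igraph::components(g)$membership
  lab[fg] <- as.integer(comp)
  lab
}

# Pixel counts per component label (named integer vector, possibly empty).
component_sizes <- function(labels) {
  fg <- labels[labels > 0L]
  if (length(fg) == 0L) return(integer(0))
  tabulate(fg)
}

# Mean of each window x window neighbourhood, replicate borders.
box_mean <- function(m, window) {
  w <- assert_odd_window(window)
  if (w == 1L) return(m)
  out <- EBImage::filter2(m, matrix(1 / w^2, w, w), boundary = "replicate")
  as.matrix(out)
}
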