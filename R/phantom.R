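# Synthetic fundus phantom generator with pixel-level ground truth.
#
# Emulates the image content the screening pipeline relies on: a circular
# fundus field on a dark surround, a red-orange background whose green
# channel is dim and falls off radially, a connected vessel tree rooted at
# the optic disk, one bright yellowish-white optic disk on the
# laterality-determined side, and optional bright yellow exudate discs in the
# central (macular) zone. Everything is deterministic for a fixed seed.

#' Phantom specification
#'
#' Geometry and photometry of a synthetic fundus image. Defaults are the
#' package's frozen study conditions: a 320 x 320 px frame with a 140 px
#' field, background green level 22 at the field centre with 30% radial
#' falloff, vessels 14 grey levels darker than the local background, an optic
#' disk of radius 16 px and +198 grey levels, exudates of +55 green contrast
#' and Gaussian noise of sigma 3 grey levels.
#'
#' @param height,width frame size in px.
#' @param laterality `"left"` or `"right"`; the optic disk sits on that side.
#' @param field_radius radius of the circular fundus field (px); default
#'   0.4375 of the smaller frame dimension.
#' @param background_mean green level at the field centre.
#' @param background_falloff fractional radial brightness falloff at the rim.
#' @param vessel_count number of vessel roots leaving the optic disk.
#' @param vessel_width_range `c(min, max)` root vessel width in px.
#' @param vessel_darkness grey-level decrement of vessels in the green channel.
#' @param od_radius optic-disk radius in px.
#' @param od_brightness green grey-level increment of the optic disk.
#' @param exudate_count number of exudate discs (0 = healthy phantom).
#' @param exudate_radius_range `c(min, max)` exudate radius in px.
#' @param exudate_contrast green grey-level increment of exudates above the
#'   local background.
#' @param noise_sigma standard deviation of the additive Gaussian noise.
#' @param seed integer RNG seed; phantoms are bit-reproducible per seed.
#' @return an object of class `fs_phantom_spec`.
#' @export
phantom_spec <- function(height = 320L, width = 320L,
                         laterality = "right",
                         field_radius = NULL,
                         background_mean = 22,
                         background_falloff = 0.3,
                         vessel_count = 6L,
                         vessel_width_range = c(2, 5),
                         vessel_darkness = 14,
                         od_radius = 16,
                         od_brightness = 198,
                         exudate_count = 0L,
                         exudate_radius_range = c(8, 20),
                         exudate_contrast = 55,
                         noise_sigma = 3,
                         seed = 1L) {
  if (is.null(field_radius)) field_radius <- 0.4375 * min(height, width)
  spec <- list(height = as.integer(height), width = as.integer(width),
               laterality = match.arg(laterality, c("left", "right")),
               field_radius = field_radius,
               background_mean = background_mean,
               background_falloff = background_falloff,
               vessel_count = as.integer(vessel_count),
               vessel_width_range = vessel_width_range,
               vessel_darkness = vessel_darkness,
               od_radius = od_radius,
               od_brightness = od_brightness,
               exudate_count = as.integer(exudate_count),
               exudate_radius_range = exudate_radius_range,
               exudate_contrast = exudate_contrast,
               noise_sigma = noise_sigma,
               seed = as.integer(seed))
  class(spec) <- "fs_phantom_spec"
  validate_phantom_spec(spec)
}

validate_phantom_spec <- function(spec) {
  stopifnot(
    "frame must be at least 64 x 64 px" = spec$height >= 64 && spec$width >= 64,
    "field must fit inside the frame" =
      spec$field_radius <= 0.5 * min(spec$height, spec$width),
    "background_mean must lie in (0, 255]" =
      spec$background_mean > 0 && spec$background_mean <= 255,
    "background_falloff must lie in [0, 1)" =
      spec$background_falloff >= 0 && spec$background_falloff < 1,
    "vessel_count must be >= 0" = spec$vessel_count >= 0,
    "vessel_width_range must be increasing and positive" =
      length(spec$vessel_width_range) == 2 && spec$vessel_width_range[1] > 0 &&
      diff(spec$vessel_width_range) >= 0,
    "optic disk must fit inside the field" =
      0.78 * spec$field_radius + spec$od_radius < spec$field_radius,
    "exudate_count must be >= 0" = spec$exudate_count >= 0,
    "exudate_radius_range must be increasing and positive" =
      length(spec$exudate_radius_range) == 2 &&
      spec$exudate_radius_range[1] > 0 && diff(spec$exudate_radius_range) >= 0,
    "exudates must fit inside the macular zone" =
      0.55 * spec$field_radius + spec$exudate_radius_range[2] < spec$field_radius,
    "noise_sigma must be >= 0" = spec$noise_sigma >= 0
  )
  spec
}

# Run fn with a private RNG stream; the caller's RNG state is untouched.
with_phantom_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

# Stamp a filled disc into a logical matrix, clipped to the frame.
stamp_disc <- function(mask, row, col, radius) {
  nr <- nrow(mask); nc <- ncol(mask)
  r0 <- max(1L, floor(row - radius)); r1 <- min(nr, ceiling(row + radius))
  c0 <- max(1L, floor(col - radius)); c1 <- min(nc, ceiling(col + radius))
  if (r0 > r1 || c0 > c1) return(mask)
  rs <- r0:r1; cs <- c0:c1
  d2 <- outer((rs - row)^2, (cs - col)^2, "+")
  mask[rs, cs] <- mask[rs, cs] | (d2 <= radius^2)
  mask
}

# Grow one vessel branch by a correlated random walk; recursive side branches.
# `env` carries the accumulating full-width mask and the centerline mask.
grow_vessel <- function(env, row, col, angle, width, field_c, field_r, depth,
                        min_width = 2) {
  steps <- 0L
  while (width >= min_width && steps < 500L) {
    env$mask <- stamp_disc(env$mask, row, col, width / 2)
    ri <- round(row); ci <- round(col)
    if (ri >= 1 && ri <= nrow(env$skel) && ci >= 1 && ci <= ncol(env$skel))
      env$skel[ri, ci] <- TRUE
    row <- row + sin(angle)
    col <- col + cos(angle)
    angle <- angle + stats::runif(1, -0.14, 0.14)
    width <- width * 0.997
    steps <- steps + 1L
    if (sqrt((row - field_c[1])^2 + (col - field_c[2])^2) >= field_r - 1.5)
      break
    if (depth < 3L && steps > 25L && stats::runif(1) < 0.02) {
      turn <- sample(c(-1, 1), 1) * stats::runif(1, 0.35, 0.9)
      grow_vessel(env, row, col, angle + turn, width * 0.72,
                  field_c, field_r, depth + 1L, min_width)
    }
  }
  invisible(env)
}

#' Generate a synthetic fundus phantom
#'
#' Renders the phantom described by `spec` and returns the 8-bit RGB image
#' together with its pixel-level ground truth. Bit-reproducible for a fixed
#' seed.
#'
#' @param spec a [phantom_spec()].
#' @return list with `image` (`H x W x 3`, 0..255) and `truth`, a list with
#'   `label` (`"healthy"`/`"pathological"`), `exudate_mask`, `vessel_mask`,
#'   `vessel_skeleton` (the drawn centerlines), `od_mask` and `od_center`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "fs_phantom_spec"))
  with_phantom_seed(spec$seed, function() render_phantom(spec))
}

render_phantom <- function(spec) {
  h <- spec$height; w <- spec$width
  ctr <- c((h + 1) / 2, (w + 1) / 2)
  R <- spec$field_radius
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  d <- sqrt((rr - ctr[1])^2 + (cc - ctr[2])^2)
  cov_field <- pmin(pmax(R + 0.5 - d, 0), 1)

  # background green with radial falloff
  bg <- spec$background_mean * (1 - spec$background_falloff * (d / R)^2)

  # optic disk on the laterality side
  sgn <- if (spec$laterality == "right") 1 else -1
  od_center <- c(ctr[1] + stats::runif(1, -0.04, 0.04) * R,
                 ctr[2] + sgn * 0.78 * R)
  d_od <- sqrt((rr - od_center[1])^2 + (cc - od_center[2])^2)
  cov_od <- pmin(pmax(spec$od_radius + 0.5 - d_od, 0), 1)

  # vessel tree rooted at the optic-disk centre
  venv <- new.env(parent = emptyenv())
  venv$mask <- matrix(FALSE, h, w)
  venv$skel <- matrix(FALSE, h, w)
  if (spec$vessel_count > 0) {
    to_centre <- atan2(ctr[1] - od_center[1], ctr[2] - od_center[2])
    for (i in seq_len(spec$vessel_count)) {
      a <- to_centre + stats::runif(1, -1.15, 1.15)
      w0 <- stats::runif(1, mean(spec$vessel_width_range),
                         spec$vessel_width_range[2])
      grow_vessel(venv, od_center[1], od_center[2], a, w0, ctr, R, 1L,
                  min_width = spec$vessel_width_range[1])
    }
  }
  vmask <- venv$mask & cov_field >= 0.5
  vskel <- venv$skel & cov_field >= 0.5

  # exudates in the macular zone, off the vessel tree, away from the disk
  cov_ex <- matrix(0, h, w)
  if (spec$exudate_count > 0) {
    for (i in seq_len(spec$exudate_count)) {
      rad <- stats::runif(1, spec$exudate_radius_range[1],
                          spec$exudate_radius_range[2])
      best <- NULL; best_overlap <- Inf
      for (try in 1:60) {
        rho <- 0.55 * R * sqrt(stats::runif(1))
        phi <- stats::runif(1, 0, 2 * pi)
        cand <- ctr + rho * c(sin(phi), cos(phi))
        if (sqrt(sum((cand - od_center)^2)) < 1.5 * spec$od_radius) next
        probe <- stamp_disc(matrix(FALSE, h, w), cand[1], cand[2], rad)
        overlap <- sum(probe & vmask)
        if (overlap < best_overlap) { best <- cand; best_overlap <- overlap }
        if (overlap == 0L) break
      }
      if (is.null(best)) best <- ctr  # degenerate geometry; keep going
      d_ex <- sqrt((rr - best[1])^2 + (cc - best[2])^2)
      cov_ex <- cov_ex + pmin(pmax(rad + 0.5 - d_ex, 0), 1)
    }
    cov_ex <- pmin(cov_ex, 1)
  }

  green <- cov_field * bg -
    spec$vessel_darkness * vmask +
    spec$od_brightness * cov_od +
    spec$exudate_contrast * cov_ex
  red <- cov_field * (165 - 25 * (d / R)^2) -
    25 * vmask + 70 * cov_od + 60 * cov_ex
  blue <- cov_field * 12 + 90 * cov_od - 2 * cov_ex

  img <- array(0, dim = c(h, w, 3))
  img[, , 1] <- red; img[, , 2] <- green; img[, , 3] <- blue
  if (spec$noise_sigma > 0)
    img <- img + stats::rnorm(length(img), 0, spec$noise_sigma)
  img <- clip8(round_half_up(img))
  storage.mode(img) <- "integer"

  truth <- list(
    label = if (spec$exudate_count > 0) "pathological" else "healthy",
    exudate_mask = cov_ex >= 0.5,
    vessel_mask = vmask,
    vessel_skeleton = vskel,
    od_mask = cov_od >= 0.5,
    od_center = od_center)
  list(image = img, truth = truth)
}

#' Generate a phantom cohort with manifest
#'
#' Writes `n` phantom images plus their ground-truth masks and a CSV manifest
#' (`path,label,laterality,seed`) to `dir`. Exactly `round(n * pathological_fraction)`
#' phantoms are pathological, carrying 1 to 4 exudate discs each; per-image
#' seeds derive reproducibly from the master seed, so the same master seed
#' always regenerates identical files.
#'
#' @param n cohort size (>= 1).
#' @param pathological_fraction fraction of pathological phantoms in `[0, 1]`.
#' @param dir output directory (created if needed).
#' @param base_spec a [phantom_spec()] supplying every non-varying parameter.
#' @param seed master integer seed.
#' @return the manifest as a data.frame (invisibly); also written to
#'   `dir/manifest.csv`.
#' @export
generate_cohort <- function(n, pathological_fraction, dir,
                            base_spec = phantom_spec(), seed = 1L) {
  stopifnot("n must be >= 1" = n >= 1,
            "pathological_fraction must lie in [0, 1]" =
              pathological_fraction >= 0 && pathological_fraction <= 1)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n_path <- round(n * pathological_fraction)
  draws <- with_phantom_seed(as.integer(seed), function() list(
    order = sample.int(n),
    seeds = sample.int(2147483646L, n),
    counts = sample(1:4, n, replace = TRUE),
    lats = sample(c("left", "right"), n, replace = TRUE)))
  labels <- c(rep("pathological", n_path),
              rep("healthy", n - n_path))[draws$order]
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- base_spec
    sp$seed <- draws$seeds[i]
    sp$laterality <- draws$lats[i]
    sp$exudate_count <- if (labels[i] == "pathological") draws$counts[i] else 0L
    sp <- validate_phantom_spec(sp)
    ph <- generate_phantom(sp)
    stem <- sprintf("phantom_%03d", i)
    path <- file.path(dir, paste0(stem, ".png"))
    write_color_image(ph$image, path)
    write_mask(ph$truth$exudate_mask,
               file.path(dir, paste0(stem, "_exudates.png")))
    write_mask(ph$truth$vessel_mask,
               file.path(dir, paste0(stem, "_vessels.png")))
    rows[[i]] <- data.frame(path = path, label = labels[i],
                            laterality = sp$laterality, seed = sp$seed,
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
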