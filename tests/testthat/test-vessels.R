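test_that("histogram equalization matches a hand-computed CDF mapping", {
  expect_identical(equalize_histogram(matrix(42L, 5, 5)), matrix(42L, 5, 5))

  two <- matrix(c(rep(0L, 8), rep(255L, 8)), 4, 4)
  expect_identical(equalize_histogram(two), two)  # extremes already extreme

  # three-level image, CDF worked out by hand:
  # levels 10 (4 px), 20 (2 px), 30 (2 px); cdf = .5, .75, 1; cdf_min = .5
  img <- matrix(c(rep(10L, 4), rep(20L, 2), rep(30L, 2)), 2, 4)
  out <- equalize_histogram(img)
  expect_identical(sort(unique(as.vector(out))),
                   c(0L, 128L, 255L))  # round(255*(0,.25,.5)/.5)
})

test_that("equalization pulls the grey-level CDF toward uniform", {
  ks_to_uniform <- function(v) {
    cdf <- cumsum(tabulate(v + 1L, 256L)) / length(v)
    max(abs(cdf - (1:256) / 256))
  }
  for (seed in 1:4) {
    g <- rand_gray(24, 24, seed = seed, lo = 80L, hi = 170L)
    expect_lte(ks_to_uniform(equalize_histogram(g)), ks_to_uniform(g) + 1e-9)
  }
})

test_that("brightness correction applies the mean-ratio gain with clipping", {
  expect_identical(brightness_correct(matrix(64L, 5, 5)), matrix(128L, 5, 5))
  expect_identical(brightness_correct(matrix(200L, 5, 5)), matrix(128L, 5, 5))
  m128 <- matrix(128L, 6, 6)
  expect_identical(brightness_correct(m128), m128)
  expect_error(brightness_correct(matrix(0L, 3, 3)), "all-zero")

  out <- brightness_correct(rand_gray(30, 30, seed = 8, lo = 40L, hi = 90L))
  expect_lt(abs(mean(out) - 128), 2)
})

test_that("matched-filter bank has the stated count, angles and symmetries", {
  bank <- matched_filter_bank()
  expect_s3_class(bank, "fs_filter_bank")
  expect_length(bank$kernels, 12L)
  expect_equal(bank$orientations, seq(0, 165, by = 15))
  for (k in bank$kernels) expect_lt(abs(sum(k)), 1e-9)

  # rotating the orientation by 90 degrees transposes the kernel
  i0 <- which(bank$orientations == 0)
  i90 <- which(bank$orientations == 90)
  expect_equal(bank$kernels[[i0]], t(bank$kernels[[i90]]), tolerance = 1e-12)

  expect_error(matched_filter_bank(sigma = -1), "sigma")
})

test_that("matched filtering is shift-invariant and orientation-selective", {
  bank <- matched_filter_bank()
  flat <- matrix(50L, 30, 30)
  expect_true(all(abs(matched_filter_response(flat, bank)) < 1e-6))

  # dark bar at ~30 degrees on a flat background (distance measured along
  # the kernel's cross-profile axis u = c*cos(theta) + r*sin(theta))
  n <- 41
  rr <- matrix(1:n, n, n); cc <- t(rr)
  theta <- 30 * pi / 180
  d <- abs((cc - 21) * cos(theta) + (rr - 21) * sin(theta))
  img <- matrix(200L, n, n); img[d <= 2] <- 80L

  centre_resp <- vapply(seq_along(bank$kernels), function(i) {
    b1 <- structure(list(kernels = bank$kernels[i],
                         orientations = bank$orientations[i],
                         sigma = bank$sigma, length = bank$length),
                    class = "fs_filter_bank")
    matched_filter_response(img, b1)[21, 21]
  }, numeric(1))
  best <- bank$orientations[which.max(centre_resp)]
  dist <- min(abs(best - 30), 180 - abs(best - 30))
  expect_lte(dist, 15)  # within one angular step

  # adding a constant leaves the response unchanged
  r1 <- matched_filter_response(img, bank)
  r2 <- matched_filter_response(img + 17L, bank)
  expect_equal(r1, r2, tolerance = 1e-6)
})

test_that("entropy threshold equals an independent exhaustive scan", {
  for (seed in 1:5) {
    resp <- withr::with_seed(seed, matrix(stats::rnorm(400)^2, 20, 20))
    expect_equal(entropy_threshold(resp), naive_entropy_threshold(resp),
                 tolerance = 1e-9)
  }
  expect_error(entropy_threshold(matrix(3.3, 5, 5)), "constant")
})

test_that("entropy threshold splits two-delta and symmetric histograms sensibly", {
  two <- matrix(c(rep(50, 60), rep(200, 40)), 10, 10)
  thr <- entropy_threshold(two)
  expect_gt(thr, 50); expect_lt(thr, 200)

  # symmetric bimodal with overlapping bumps (unique interior maximum):
  # threshold near the midpoint
  sym <- withr::with_seed(11, c(stats::rnorm(3000, 60, 25), stats::rnorm(3000, 196, 25)))
  sym <- matrix(pmin(pmax(sym, 0), 255), 60, 100)
  thr2 <- entropy_threshold(sym)
  expect_gt(thr2, 100); expect_lt(thr2, 156)
})

test_that("small-component pruning follows size, idempotence and monotonicity", {
  m <- matrix(FALSE, 10, 10)
  expect_identical(remove_small_components(m, 5), m)

  m[3, 3:7] <- TRUE  # one 5-px component
  expect_identical(remove_small_components(m, 1), m)
  expect_identical(remove_small_components(m, 10), matrix(FALSE, 10, 10))
  expect_identical(remove_small_components(m, 5), m)

  for (seed in 1:3) {
    rm_ <- rand_mask(18, 18, seed = seed, p = 0.25)
    pruned <- remove_small_components(rm_, 4)
    expect_identical(remove_small_components(pruned, 4), pruned)  # idempotent
    stricter <- remove_small_components(rm_, 8)
    expect_true(all(pruned | !stricter))  # monotone: larger cut, fewer pixels
  }
})

test_that("component labelling agrees with a flood-fill oracle", {
  for (seed in 1:3) {
    m <- rand_mask(15, 15, seed = 10 + seed, p = 0.2)
    lab <- label_components(m)
    expect_identical(max(lab), flood_count(m))
    expect_identical(lab > 0, m)
  }
  diag2 <- matrix(FALSE, 4, 4); diag2[1, 1] <- diag2[2, 2] <- TRUE
  expect_identical(max(label_components(diag2)), 1L)  # 8-connectivity
})

test_that("vessel extraction equals the manual stage chain", {
  ph <- generate_phantom(phantom_spec(seed = 21))
  cfg <- pipeline_config()
  auto <- extract_vessels(ph$image, cfg, intermediates = TRUE)

  g <- to_green_gray(ph$image)
  g <- median_denoise(g, cfg$median_window)
  g <- equalize_histogram(g)
  g <- brightness_correct(g, cfg$brightness_target)
  bank <- matched_filter_bank(cfg$mf_sigma, cfg$mf_length, cfg$mf_orientations)
  resp <- matched_filter_response(g, bank)
  thr <- entropy_threshold(resp)
  manual <- remove_small_components(resp > thr, cfg$vessel_min_length)
  expect_identical(as.logical(auto), as.logical(manual))

  # the mask is a subset of the above-threshold response support
  ii <- attr(auto, "intermediates")
  expect_true(all(!auto | (ii$response > ii$threshold)))
})

test_that("vessel extraction recovers the phantom vessel skeleton", {
  for (seed in c(5, 23)) {
    ph <- generate_phantom(phantom_spec(seed = seed))
    mask <- extract_vessels(ph$image)
    sk <- ph$truth$vessel_skeleton
    recall <- sum(mask & sk) / sum(sk)
    expect_gte(recall, 0.7)
  }
})
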