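test_that("vessel masking blacks out exactly the mask support", {
  g <- rand_gray(12, 12, seed = 1, lo = 1L, hi = 255L)
  none <- matrix(FALSE, 12, 12)
  expect_identical(mask_out_vessels(g, none), g)
  expect_identical(mask_out_vessels(g, !none), matrix(0L, 12, 12))

  m <- rand_mask(12, 12, seed = 2)
  out <- mask_out_vessels(g, m)
  expect_true(all(out[m] == 0L))
  expect_identical(out[!m], g[!m])
  expect_identical(out != g, m & g != 0L)

  expect_error(mask_out_vessels(g, matrix(FALSE, 3, 3)), "shape")
})

test_that("fixed binarization uses a strict threshold", {
  img <- matrix(c(12L, 13L, 14L, 255L), 2, 2)
  out <- binarize_fixed(img, 13L)
  expect_identical(as.vector(out), c(FALSE, FALSE, TRUE, TRUE))
  expect_false(any(binarize_fixed(matrix(0L, 5, 5))))

  g <- rand_gray(20, 20, seed = 6)
  for (t in c(0L, 13L, 200L))
    expect_identical(sum(binarize_fixed(g, t)), sum(g > t))
})

test_that("local variance map matches the naive two-pass oracle", {
  expect_identical(local_variance_map(matrix(TRUE, 8, 8), 5),
                   matrix(0L, 8, 8))
  expect_identical(local_variance_map(matrix(FALSE, 8, 8), 5),
                   matrix(0L, 8, 8))

  # straight vertical edge: variance peaks along the boundary columns
  edge <- cbind(matrix(FALSE, 12, 6), matrix(TRUE, 12, 6))
  vm <- local_variance_map(edge, 5)
  expect_identical(vm, naive_variance_map(edge, 5))
  expect_true(all(vm[, 6] >= vm[, 2]))

  for (seed in 1:3)
    for (w in c(3L, 5L)) {
      m <- rand_mask(14, 17, seed = 20 + seed, p = 0.4)
      expect_identical(local_variance_map(m, w), naive_variance_map(m, w))
    }
})

test_that("optic-disk anchor follows the laterality scan order", {
  empty <- matrix(FALSE, 8, 8)
  expect_null(locate_optic_disk_anchor(empty, "left"))

  one <- matrix(FALSE, 20, 20); one[10, 5] <- TRUE
  expect_identical(locate_optic_disk_anchor(one, "left"),
                   c(row = 10L, col = 5L))

  two <- matrix(FALSE, 60, 100)
  two[1, 91] <- TRUE; two[51, 100] <- TRUE
  expect_identical(locate_optic_disk_anchor(two, "right"),
                   c(row = 51L, col = 100L))
  expect_identical(locate_optic_disk_anchor(two, "left"),
                   c(row = 1L, col = 91L))

  # swapped side convention
  expect_identical(
    locate_optic_disk_anchor(two, "left",
                             side_map = list(left = "right", right = "left")),
    c(row = 51L, col = 100L))
})

test_that("optic-disk removal blanks a centred, border-clipped square", {
  big <- matrix(TRUE, 300, 300)
  out <- remove_optic_disk(big, c(150, 150), 80)
  expect_identical(sum(!out), 6400L)
  expect_false(any(out[111:190, 111:190]))

  corner <- remove_optic_disk(big, c(1, 1), 80)
  expect_identical(sum(!corner), 41L * 41L)

  empty <- matrix(FALSE, 50, 50)
  expect_identical(remove_optic_disk(empty, c(25, 25), 10), empty)
  expect_message(same <- remove_optic_disk(big, NULL, 80), "anchor")
  expect_identical(same, big)
  expect_error(remove_optic_disk(big, c(0, 5), 80), "outside")

  # never adds foreground
  m <- rand_mask(40, 40, seed = 3)
  expect_true(all(!(remove_optic_disk(m, c(20, 20), 15) & !m)))
})

test_that("classification counts surviving foreground monotonically", {
  expect_identical(classify_retina(matrix(FALSE, 10, 10)), "healthy")
  one <- matrix(FALSE, 10, 10); one[5, 5] <- TRUE
  expect_identical(classify_retina(one, 1), "pathological")

  m <- matrix(FALSE, 12, 12)
  m[2, 2:4] <- TRUE                # 3-px component
  m[8, 3:9] <- TRUE                # 7-px component
  expect_identical(classify_retina(m, 5), "pathological")
  expect_identical(classify_retina(m, 8), "healthy")

  # monotone: adding foreground never flips pathological -> healthy
  for (seed in 1:5) {
    base <- rand_mask(15, 15, seed = 30 + seed, p = 0.05)
    extra <- base | rand_mask(15, 15, seed = 60 + seed, p = 0.05)
    for (a in c(1L, 3L, 6L))
      if (classify_retina(base, a) == "pathological")
        expect_identical(classify_retina(extra, a), "pathological")
  }
})

test_that("overlay marks exactly the lesion support in pure blue", {
  img <- rand_rgb(10, 10, seed = 4)
  none <- matrix(FALSE, 10, 10)
  expect_identical(render_overlay(img, none), img)

  blue <- render_overlay(img, !none)
  expect_true(all(blue[, , 1] == 0L) && all(blue[, , 2] == 0L) &&
                all(blue[, , 3] == 255L))

  m <- rand_mask(10, 10, seed = 5)
  out <- render_overlay(img, m)
  is_blue <- out[, , 1] == 0L & out[, , 2] == 0L & out[, , 3] == 255L
  # blue set equals the mask support (up to input pixels already pure blue)
  expect_true(all(is_blue[m]))
  expect_identical(out[, , 1][!m], img[, , 1][!m])
  expect_error(render_overlay(img, matrix(FALSE, 3, 3)), "shape")
})

test_that("lesion detection equals the manual stage chain", {
  ph <- generate_phantom(phantom_spec(seed = 33, exudate_count = 1))
  cfg <- pipeline_config()
  pre <- preprocess_retina(ph$image, cfg)
  vm <- extract_vessels(ph$image, cfg)
  auto <- detect_lesions(pre, vm, "right", cfg)

  manual <- mask_out_vessels(pre, vm)
  manual <- binarize_fixed(manual, cfg$lesion_threshold)
  anchor <- locate_optic_disk_anchor(manual, "right", cfg$laterality_side_map)
  manual <- remove_optic_disk(manual, anchor, cfg$od_square_side)
  expect_identical(auto$decision, classify_retina(manual, cfg$min_lesion_area))
  expect_identical(auto$lesion_mask,
                   remove_small_components(manual, cfg$min_lesion_area))
  expect_identical(auto$od_anchor, anchor)
})

test_that("phantoms with and without exudates are classified correctly", {
  cfg <- pipeline_config()

  ph1 <- generate_phantom(phantom_spec(seed = 41, exudate_count = 1,
                                       exudate_radius_range = c(15, 15)))
  pre <- preprocess_retina(ph1$image, cfg)
  vm <- extract_vessels(ph1$image, cfg)
  det <- detect_lesions(pre, vm, "right", cfg)
  expect_identical(det$decision, "pathological")
  expect_gt(sum(det$lesion_mask & ph1$truth$exudate_mask), 0)

  ph0 <- generate_phantom(phantom_spec(seed = 42, exudate_count = 0))
  det0 <- detect_lesions(preprocess_retina(ph0$image, cfg),
                         extract_vessels(ph0$image, cfg), "right", cfg)
  expect_identical(det0$decision, "healthy")
})

test_that("exudate-free phantoms screen healthy across seeds", {
  healthy <- 0L
  n <- 20L
  for (s in seq_len(n)) {
    lat <- if (s %% 2 == 0) "left" else "right"
    ph <- generate_phantom(phantom_spec(seed = 500 + s, exudate_count = 0,
                                        laterality = lat))
    res <- screen_retina(ph$image, lat)
    healthy <- healthy + (res$decision == "healthy")
  }
  expect_gte(healthy / n, 0.95)
})
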