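test_that("voxel-summation volume matches hand-computed examples", {
  one <- mask_series(list(matrix(rep(c(1L, 0L), c(200, 56)), 16, 16)),
                     pixel_spacing_x = 1, pixel_spacing_y = 1, slice_z = 1)
  v <- compute_volume(one, select_kidney_region(one, 1))
  expect_equal(v$volume_mm3, 200)
  expect_equal(v$volume_ml, 0.2)

  masks <- lapply(c(100, 200, 300), function(n) {
    m <- matrix(0L, 20, 20); m[seq_len(n)] <- 1L; m
  })
  s <- mask_series(masks, 0.7, 0.7, 1.0)
  v2 <- compute_volume(s, select_kidney_region(s, 1))
  expect_equal(v2$volume_mm3, 600 * 0.49)
  expect_equal(v2$n_slices_used, 3L)

  empty <- mask_series(list(matrix(0L, 4, 4)), 1, 1, 1)
  expect_warning(reg <- select_kidney_region(empty, 200), "floor")
  v3 <- compute_volume(empty, reg)
  expect_equal(v3$volume_ml, 0)
  expect_equal(v3$n_slices_used, 0L)
})

test_that("volume equals the brute-force voxel iteration on randomized series", {
  for (i in 1:25) {
    s <- random_mask_series(n_slices = sample(3:12, 1), seed = 100 + i)
    reg <- select_kidney_region(s, min_pixel_count = sample(0:40, 1))
    v <- compute_volume(s, reg)
    expect_identical(v$volume_ml, brute_force_volume_ml(s, reg$run))
  }
})

test_that("run detection matches hand-worked profiles including ties", {
  expect_equal(select_kidney_region(c(0, 0, 250, 300, 280, 0, 0, 220, 0))$run,
               c(3L, 5L))
  expect_equal(select_kidney_region(c(500, 500, 500))$run, c(1L, 3L))
  expect_equal(formals(select_kidney_region)$min_pixel_count, 200)
  # two length-1 runs with equal sums: earlier table position wins
  expect_equal(select_kidney_region(c(300, 199, 300))$run, c(1L, 1L))
  # larger pixel sum breaks the length tie
  expect_equal(select_kidney_region(c(300, 0, 400))$run, c(3L, 3L))
})

test_that("area-based floor reproduces the pixel floor on the clinical grid", {
  masks <- lapply(c(150, 250, 400, 100), function(n) {
    m <- matrix(0L, 32, 32); m[seq_len(n)] <- 1L; m
  })
  s <- mask_series(masks, 0.7, 0.7, 1)
  a <- select_kidney_region(s, min_pixel_count = 200)
  b <- select_kidney_region(s, min_area_mm2 = 200 * 0.49)
  expect_equal(a$run, b$run)
  expect_error(select_kidney_region(c(1, 2, 3), min_area_mm2 = 10),
               "mask_series")
})

test_that("adding foreground pixels to an in-run slice never decreases the volume", {
  set.seed(77)
  for (i in 1:10) {
    s <- random_mask_series(8, seed = 300 + i)
    reg <- select_kidney_region(s, min_pixel_count = 10)
    if (is.null(reg$run)) next
    v1 <- compute_volume(s, reg)$volume_ml
    k <- reg$run[1]
    m <- s$masks[[k]]
    zero <- which(m == 0)
    if (length(zero) == 0) next
    m[zero[1]] <- 1L
    s2 <- mask_series(replace(s$masks, k, list(m)), s$pixel_spacing_x,
                      s$pixel_spacing_y, s$slice_z)
    v2 <- compute_volume(s2, select_kidney_region(s2, min_pixel_count = 10))
    expect_gte(v2$volume_ml, v1)
  }
})

test_that("the semi-automated estimator reduces to full voxel summation at full sampling", {
  ph <- tiny_phantom()
  ts <- truth_mask_series(ph, "right")
  semi <- semi_automated_volume(ts, sampling_interval_mm = 4)  # = slice spacing
  full <- compute_volume(ts, select_kidney_region(ts, min_pixel_count = 1))
  expect_equal(semi$volume_ml, full$volume_ml)
  expect_equal(formals(semi_automated_volume)$sampling_interval_mm, 3)
})

test_that("3 mm sampling agrees with 1 mm voxel summation within 3% on analytic phantoms", {
  sp <- phantom_spec(image_height = 160, image_width = 160, n_slices = 120,
                     pixel_spacing_x = 1, pixel_spacing_y = 1,
                     slice_spacing = 1,
                     kidney_semi_axes_left = c(30, 25, 50),
                     kidney_semi_axes_right = c(28, 23, 47),
                     kidney_center_left = c(42, 1.3, 60.7),
                     kidney_center_right = c(-42, 0, 59.1),
                     noise_sigma = 0)
  ph <- generate_phantom(sp)
  for (side in c("left", "right")) {
    ts <- truth_mask_series(ph, side)
    v1 <- compute_volume(ts, select_kidney_region(ts, min_pixel_count = 1))
    v3 <- semi_automated_volume(ts, sampling_interval_mm = 3)
    expect_lt(abs(v3$volume_ml - v1$volume_ml) / v1$volume_ml, 0.03)
  }
})

test_that("an interval that is not a multiple of the slice spacing records its offset", {
  ph <- tiny_phantom()  # 4 mm slice spacing
  ts <- truth_mask_series(ph, "left")
  v <- semi_automated_volume(ts, sampling_interval_mm = 3)
  off <- attr(v, "sampling_offset_mm")
  expect_false(is.null(off))
  expect_lte(off, 2)  # never farther than half a gap
})

test_that("mask series validate their spacing metadata", {
  expect_error(mask_series(list(matrix(0, 2, 2)), -1, 1, 1))
  expect_error(compute_volume(structure(list(), class = "list")))
})
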