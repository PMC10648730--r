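test_that("vertical split matches the 5% overlap arithmetic", {
  s <- matrix(seq_len(512 * 512), 512)
  h <- split_slice(s, 0.05)
  expect_equal(ncol(h$right), 269)  # 256 + round(0.05 * 256)
  expect_equal(ncol(h$left), 269)
  expect_equal(h$column_ranges$right, c(1L, 269L))
  expect_equal(h$column_ranges$left, c(244L, 512L))

  h0 <- split_slice(s, 0)
  expect_equal(h0$column_ranges$right, c(1L, 256L))
  expect_equal(h0$column_ranges$left, c(257L, 512L))

  expect_equal(formals(split_slice)$overlap_fraction, 0.05)
  expect_error(split_slice(matrix(0, 4, 5)), "even")
  expect_error(split_slice(s, 0.5))
})

test_that("split followed by reassembly is the identity for any overlap", {
  set.seed(3)
  for (ov in c(0, 0.03, 0.05, 0.2, 0.49)) {
    s <- matrix(rnorm(64 * 48), 48, 64)
    expect_identical(reassemble_halves(split_slice(s, ov)), s,
                     label = paste("overlap", ov))
  }
})

test_that("normalization maps intensity extremes to [0, 1] and handles constants", {
  img <- matrix(c(-100, 35), 16, 16)
  out <- normalize_and_resize(img, c(16, 16))
  expect_setequal(unique(as.vector(out)), c(0, 1))
  expect_true(all(normalize_and_resize(matrix(7, 8, 8), c(8, 8)) == 0))
  half <- matrix(rnorm(512 * 269), 512, 269)
  expect_equal(dim(normalize_and_resize(half, c(512, 256))), c(512, 256))
  expect_error(normalize_and_resize(matrix(c(1, NA), 2, 2), c(2, 2)),
               "non-finite")
})

test_that("masks are resized nearest-neighbour and never intensity-scaled", {
  m <- matrix(0L, 64, 64); m[20:40, 20:40] <- 1L
  out <- normalize_and_resize(m, c(32, 32), mask = TRUE)
  expect_true(all(out %in% c(0L, 1L)))
  # identity-shape resize preserves the pixel count exactly
  expect_equal(sum(normalize_and_resize(m, c(64, 64), mask = TRUE)), sum(m))
})

test_that("training-set assembly samples the kidney extent at the configured interval", {
  ph <- tiny_phantom()
  # kidney extent in z: about 2 * 50 mm; at 10 mm intervals -> 10 or 11 slices
  ds <- build_training_set(ph, side = "left", target_shape = c(128, 64),
                           sampling_interval_mm = 10, seed = 5)
  expect_true(ds$n_positive %in% c(10, 11))
  expect_true(all(vapply(ds$slices, function(s)
    all(s$image >= 0 & s$image <= 1), logical(1))))
  # positives have nonempty masks, negatives empty ones
  for (s in ds$slices) {
    if (s$has_kidney) expect_gt(sum(s$mask), 0) else expect_equal(sum(s$mask), 0)
  }
  # negatives come only from slices without kidney on that side
  counts <- apply(ph$truth$masks_left, 3, sum)
  for (s in ds$slices) {
    if (!s$has_kidney) expect_equal(counts[s$source_slice_index], 0)
  }
})

test_that("the negative-control share defaults to the clinical datasets' ratio", {
  # 1603 negatives of 5809 right-kidney slices ~ 0.28
  expect_equal(formals(build_training_set)$negative_fraction, 0.28)
  ph <- tiny_phantom()
  ds <- build_training_set(ph, "right", target_shape = c(128, 64), seed = 3)
  frac <- ds$n_negative / length(ds$slices)
  expect_lt(abs(frac - 0.28), 0.08)
})

test_that("dataset assembly is deterministic given a seed", {
  ph <- tiny_phantom()
  d1 <- build_training_set(ph, "right", target_shape = c(128, 64), seed = 9)
  d2 <- build_training_set(ph, "right", target_shape = c(128, 64), seed = 9)
  expect_identical(lapply(d1$slices, `[[`, "source_slice_index"),
                   lapply(d2$slices, `[[`, "source_slice_index"))
  expect_identical(d1$slices[[1]]$image, d2$slices[[1]]$image)
})

test_that("a volume with no kidney on one side yields positives = 0 and a warning", {
  sp <- phantom_spec_small()
  ph <- tiny_phantom()
  ph_nok <- ph
  ph_nok$truth$masks_left <- array(0L, dim(ph$truth$masks_left))
  # warns both about the kidney-free volume and the empty positive set
  expect_warning(expect_warning(
    ds <- build_training_set(ph_nok, "left", target_shape = c(128, 64))))
  expect_equal(ds$n_positive, 0)
})

test_that("augmentation applies at most one transform and preserves mask semantics", {
  set.seed(11)
  img <- matrix(runif(32 * 32), 32)
  msk <- matrix(0L, 32, 32); msk[10:20, 10:20] <- 1L

  # probability 0: identity
  a0 <- augment(img, msk, probability = 0)
  expect_identical(a0$image, img)
  expect_equal(a0$applied, "none")

  # intensity-only branches leave the mask untouched; output stays in [0,1]
  seen <- character(0)
  for (i in 1:50) {
    a <- augment(img, msk, probability = 1)
    seen <- c(seen, a$applied)
    expect_true(all(a$image >= 0 & a$image <= 1))
    if (a$applied %in% c("gaussian_blur", "multiplicative_noise")) {
      expect_identical(a$mask, msk)
    } else {
      expect_true(all(a$mask %in% c(0L, 1L)))
    }
  }
  expect_setequal(unique(seen), c("optical_distortion",
                                  "multiplicative_noise", "gaussian_blur"))
})

test_that("augmentation frequency is binomial around 0.5", {
  set.seed(21)
  img <- matrix(runif(16 * 16), 16)
  n <- 10000
  hits <- 0
  for (i in seq_len(n)) {
    if (augment(img, probability = 0.5)$applied != "none") hits <- hits + 1
  }
  ci <- qbinom(c(0.005, 0.995), n, 0.5)
  expect_gte(hits, ci[1])
  expect_lte(hits, ci[2])
})
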