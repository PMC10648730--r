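test_that("hyperparameter container validates its fields", {
  hp <- hyperparameters()
  expect_equal(hp$learning_rate, 0.15)
  expect_equal(hp$batch_size, 12L)
  expect_equal(hp$start_feature_maps, 32L)
  expect_equal(hp$dropout_rate, 0.1)
  expect_error(hyperparameters(learning_rate = -1))
  expect_error(hyperparameters(dropout_rate = 1))
})

test_that("encoder feature schedule follows the doubling rule from the start width", {
  net <- build_unet(hyperparameters(start_feature_maps = 8), c(64, 32),
                    seed = 1)
  a <- unet_audit(net)
  expect_equal(a$encoder_schedule, c(8, 8, 16, 16, 32, 32, 64, 64, 128, 128))
  # transpose convs carry the channel count of the preceding conv output
  expect_equal(dim(net$params$u1_w)[3:4], c(128, 128))
  expect_equal(dim(net$params$u4_w)[3:4], c(16, 16))
})

test_that("indivisible input shapes are rejected with the constraint named", {
  expect_error(build_unet(hyperparameters(start_feature_maps = 4), c(100, 64)),
               "divisible by 16")
})

test_that("the sigmoid output head keeps every value strictly inside (0, 1)", {
  net <- build_unet(hyperparameters(start_feature_maps = 2, dropout_rate = 0),
                    c(32, 16), seed = 2)
  x <- array(runif(32 * 16 * 2), c(32, 16, 2, 1))
  p <- renalvol:::unet_forward(net, x, training = FALSE)$p
  expect_equal(dim(p), c(32, 16, 2, 1))
  expect_true(all(p > 0 & p < 1))
})

test_that("training reduces the validation loss on a small phantom dataset", {
  ph <- tiny_phantom(noise_sigma = 20, seed = 3)
  ds <- build_training_set(ph, "left", target_shape = c(128, 64),
                           sampling_interval_mm = 10, seed = 4)
  hp <- hyperparameters(learning_rate = 2e-3, dropout_rate = 0.1,
                        start_feature_maps = 8, batch_size = 4)
  net <- build_unet(hp, c(128, 64), seed = 5)
  tr <- train_unet(net, ds, max_epochs = 4, augment_prob = 0, seed = 5)
  expect_true(all(is.finite(tr$history$train_loss)))
  expect_lt(tr$best_val_loss, tr$history$val_loss[1])
  expect_equal(formals(train_unet)$patience, 30)
})

test_that("training on identical all-negative images drives the output toward zero", {
  img <- matrix(0.5, 32, 16)
  slices <- lapply(1:8, function(i) {
    structure(list(image = img, mask = matrix(0L, 32, 16), side = "left",
                   source_slice_index = i, has_kidney = FALSE),
              class = "side_slice")
  })
  ds <- structure(list(side = "left", slices = slices, n_positive = 0L,
                       n_negative = 8L, target_shape = c(32, 16)),
                  class = "side_dataset")
  net <- build_unet(hyperparameters(learning_rate = 0.05, dropout_rate = 0,
                                    start_feature_maps = 2, batch_size = 2),
                    c(32, 16), seed = 6)
  tr <- train_unet(net, ds, max_epochs = 25, augment_prob = 0, seed = 6)
  expect_lt(tr$best_val_loss, 0.1)
  p <- renalvol:::unet_forward(tr$net, array(img, c(32, 16, 1, 1)),
                               training = FALSE)$p
  expect_lt(mean(p), 0.1)
})

test_that("empty datasets and shape mismatches are rejected before training", {
  net <- build_unet(hyperparameters(start_feature_maps = 2), c(32, 16))
  empty <- structure(list(side = "left", slices = list()),
                     class = "side_dataset")
  expect_error(train_unet(net, empty), "empty")
  ph <- tiny_phantom()
  ds <- build_training_set(ph, "left", target_shape = c(64, 32))
  expect_error(train_unet(net, ds), "does not match")
})

test_that("mask prediction is deterministic and respects the threshold default", {
  net <- build_unet(hyperparameters(start_feature_maps = 2, dropout_rate = 0.3),
                    c(32, 16), seed = 8)
  img <- matrix(runif(32 * 16), 32, 16)
  m1 <- predict_mask(net, img)
  m2 <- predict_mask(net, img)
  expect_identical(m1, m2)
  expect_true(all(m1 %in% c(0L, 1L)))
  expect_equal(formals(predict_mask)$threshold, 0.5)
  # mapping back to the source geometry keeps the mask binary
  m3 <- predict_mask(net, img, out_shape = c(128, 64))
  expect_equal(dim(m3), c(128, 64))
  expect_true(all(m3 %in% c(0L, 1L)))
  expect_error(predict_mask(net, matrix(0, 16, 16)), "does not match")
})

test_that("training with a fixed seed reproduces the loss history exactly", {
  ph <- tiny_phantom()
  ds <- build_training_set(ph, "right", target_shape = c(128, 64), seed = 2)
  ds$slices <- ds$slices[1:6]
  hp <- hyperparameters(learning_rate = 1e-3, dropout_rate = 0.1,
                        start_feature_maps = 4, batch_size = 2)
  run <- function() {
    net <- build_unet(hp, c(128, 64), seed = 11)
    train_unet(net, ds, max_epochs = 2, augment_prob = 0.5, seed = 11)$history
  }
  expect_identical(run(), run())
})
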