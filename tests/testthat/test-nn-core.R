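# The compiled convolution kernels are checked against the independent plain-R
# shifted-gemm implementation, and the full network backward pass against
# central finite differences.

test_that("compiled 3x3 convolution matches the plain-R reference", {
  set.seed(1)
  x <- array(rnorm(12 * 16 * 3 * 4), c(12, 16, 3, 4))
  w <- array(rnorm(3 * 3 * 4 * 5), c(3, 3, 4, 5))
  b <- rnorm(5)
  expect_equal(renalvol:::conv3x3_forward(x, w, b),
               renalvol:::conv3x3_forward_r(x, w, b), tolerance = 1e-5)
  dy <- array(rnorm(12 * 16 * 3 * 5), c(12, 16, 3, 5))
  g <- renalvol:::conv3x3_backward(x, w, dy)
  gr <- renalvol:::conv3x3_backward_r(x, w, dy)
  expect_equal(g$dx, gr$dx, tolerance = 1e-5)
  expect_equal(g$dw, gr$dw, tolerance = 1e-5)
  expect_equal(g$db, gr$db, tolerance = 1e-5)
})

test_that("max pooling forward/backward route values and gradients correctly", {
  x <- array(0, c(4, 4, 1, 1))
  x[, , 1, 1] <- matrix(c(1, 2, 3, 4,
                          5, 6, 7, 8,
                          9, 10, 11, 12,
                          13, 14, 15, 16), 4, byrow = TRUE)
  out <- renalvol:::maxpool_forward(x)
  expect_equal(as.vector(out$y[, , 1, 1]), c(6, 14, 8, 16))
  dy <- out$y * 0 + 1
  dx <- renalvol:::maxpool_backward(out$which, dy, 4, 4)
  expect_equal(sum(dx), 4)
  expect_equal(dx[2, 2, 1, 1], 1)  # gradient lands on the maximum
  expect_equal(dx[1, 1, 1, 1], 0)
})

test_that("network gradients agree with central finite differences", {
  net <- build_unet(hyperparameters(dropout_rate = 0.2, start_feature_maps = 2,
                                    batch_size = 2), c(16, 16), seed = 7)
  net$exact <- TRUE  # double-precision reference convolutions
  set.seed(42)
  x <- array(runif(16 * 16 * 2), c(16, 16, 2, 1))
  y <- array(rbinom(16 * 16 * 2, 1, 0.3), c(16, 16, 2, 1))
  loss_at <- function(n2) {
    set.seed(99)  # fixes the dropout masks
    fw <- renalvol:::unet_forward(n2, x, training = TRUE)
    renalvol:::bce_loss(fw$p, y)
  }
  set.seed(99)
  fw <- renalvol:::unet_forward(net, x, training = TRUE)
  grads <- renalvol:::unet_backward(net, fw$cache,
                                    renalvol:::bce_sigmoid_grad(fw$p, y))
  # exact mode permits a small eps; the loss is sharply curved around
  # weights feeding training-mode batch norm, so a larger step would be
  # truncation-limited
  eps <- 1e-6
  set.seed(1)
  for (nm in c("e1_w", "e5_w", "u2_w", "d1_w", "d7_w", "o_w",
               "bn_e3_gamma", "bn_d4_beta")) {
    k <- sample(length(net$params[[nm]]), 1)
    n2 <- net
    n2$params[[nm]][k] <- n2$params[[nm]][k] + eps
    lp <- loss_at(n2)
    n2$params[[nm]][k] <- n2$params[[nm]][k] - 2 * eps
    lm <- loss_at(n2)
    num <- (lp - lm) / (2 * eps)
    expect_lt(abs(grads[[nm]][k] - num) / max(abs(num), 1e-4), 1e-4,
              label = paste("gradient of", nm))
  }
})

test_that("binary cross-entropy and its logit gradient are consistent", {
  p <- c(0.1, 0.5, 0.9)
  t <- c(0, 1, 1)
  expect_equal(renalvol:::bce_loss(p, t),
               -mean(t * log(p) + (1 - t) * log(1 - p)))
  expect_equal(renalvol:::bce_sigmoid_grad(p, t), (p - t) / 3)
  expect_true(is.finite(renalvol:::bce_loss(c(0, 1), c(0, 1))))
})

test_that("batch normalization normalizes per channel and tracks running stats", {
  set.seed(5)
  x <- array(rnorm(8 * 8 * 4 * 3, mean = 2, sd = 3), c(8, 8, 4, 3))
  run <- list(mean = rep(0, 3), var = rep(1, 3))
  out <- renalvol:::batchnorm_forward(x, gamma = rep(1, 3), beta = rep(0, 3),
                                      running = run, training = TRUE)
  xm <- renalvol:::as_mat(out$y)
  expect_equal(colMeans(xm), rep(0, 3), tolerance = 1e-10)
  expect_equal(apply(xm, 2, sd), rep(1, 3), tolerance = 1e-2)
  expect_false(all(out$running$mean == 0))
})
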