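test_that("dice matches its definition and boundary conventions", {
  m <- matrix(0L, 8, 8); m[2:4, 2:4] <- 1L
  expect_equal(dice(m, m), 1)
  n <- matrix(0L, 8, 8); n[6:8, 6:8] <- 1L
  expect_equal(dice(m, n), 0)
  a <- matrix(0L, 4, 4); a[1:4] <- 1L        # |A| = 4
  b <- matrix(0L, 4, 4); b[3:8] <- 1L        # |B| = 6, intersection = 2
  expect_equal(dice(a, b), 2 * 2 / (4 + 6))
  b2 <- matrix(0L, 4, 4); b2[c(1, 2, 3, 5, 6, 7)] <- 1L  # intersection = 3
  expect_equal(dice(a, b2), 0.6)
  expect_equal(dice(a, b2), dice(b2, a))
  z <- matrix(0L, 4, 4)
  expect_equal(dice(z, z), 1)  # agreement on absence
  expect_error(dice(a, matrix(0L, 3, 3)), "shapes differ")
})

test_that("both ICC forms match the explicit double-loop ANOVA oracle", {
  set.seed(101)
  for (i in 1:20) {
    x <- cbind(rnorm(10, 100, 30), rnorm(10, 100, 30))
    x[, 2] <- 0.7 * x[, 1] + 0.3 * x[, 2] + rnorm(10, 2, 5)
    ms <- anova_ms_oracle(x)
    n <- 10; k <- 2
    expected_c <- (ms$msr - ms$mse) / (ms$msr + (k - 1) * ms$mse)
    expected_a <- (ms$msr - ms$mse) /
      (ms$msr + (k - 1) * ms$mse + k / n * (ms$msc - ms$mse))
    pm <- paired_measurements(x[, 1], x[, 2])
    expect_equal(icc(pm, "consistency")$value, expected_c, tolerance = 1e-10)
    expect_equal(icc(pm, "absolute")$value, expected_a, tolerance = 1e-10)
  }
})

test_that("ICC responds to systematic offsets the way the two forms should", {
  a <- c(120, 150, 180, 140, 160, 135)
  pm_same <- paired_measurements(a, a)
  expect_equal(icc(pm_same, "consistency")$value, 1)
  expect_equal(icc(pm_same, "absolute")$value, 1)
  pm_shift <- paired_measurements(a, a + 12)
  expect_equal(icc(pm_shift, "consistency")$value, 1)
  expect_lt(icc(pm_shift, "absolute")$value, 1)
  # absolute <= consistency whenever a systematic offset exists
  set.seed(5)
  b <- a + 8 + rnorm(6, 0, 3)
  pm <- paired_measurements(a, b)
  expect_lte(icc(pm, "absolute")$value, icc(pm, "consistency")$value)
})

test_that("ICC confidence intervals bracket the estimate", {
  set.seed(9)
  a <- rnorm(15, 160, 40); b <- a + rnorm(15, 3, 10)
  for (form in c("consistency", "absolute")) {
    r <- icc(paired_measurements(a, b), form)
    expect_lt(r$ci[1], r$value)
    expect_gt(r$ci[2], r$value)
    expect_lte(r$ci[2], 1)
  }
})

test_that("agreement levels follow the fixed thresholds", {
  expect_equal(renalvol:::icc_level(0.92), "excellent")
  expect_equal(renalvol:::icc_level(0.89), "good")
  expect_equal(renalvol:::icc_level(0.93), "excellent")
  expect_equal(renalvol:::icc_level(0.75), "moderate")
  expect_equal(renalvol:::icc_level(0.3), "poor")
})

test_that("zero between-subject variance yields an explicit degenerate result", {
  pm <- paired_measurements(rep(5, 4), rep(5, 4))
  r <- icc(pm, "consistency")
  expect_true(r$degenerate)
  expect_true(is.na(r$value))
})

test_that("Bland-Altman limits match the hand calculation", {
  pm <- paired_measurements(c(10, 10, 10), c(8, 10, 12))  # differences -2,0,2
  ba <- bland_altman(pm)
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$sd_diff, 2)
  expect_equal(ba$lower, -3.92)
  expect_equal(ba$upper, 3.92)
  same <- bland_altman(paired_measurements(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$mean_diff, 0)
  expect_equal(c(same$lower, same$upper), c(0, 0))
  # sign convention: differences are b - a
  ba2 <- bland_altman(paired_measurements(c(0, 0), c(1, 3)))
  expect_equal(ba2$mean_diff, 2)
})

test_that("Bland-Altman limits contain about 95% of Gaussian differences", {
  set.seed(31)
  a <- rnorm(4000, 150, 30)
  b <- a + rnorm(4000, 2, 8)
  ba <- bland_altman(paired_measurements(a, b))
  inside <- mean(ba$data$difference >= ba$lower &
                   ba$data$difference <= ba$upper)
  expect_gt(inside, 0.94)
  expect_lt(inside, 0.97)
})

test_that("error metrics match the worked example and exclude zero references", {
  pm <- paired_measurements(c(100, 200), c(110, 190))
  em <- error_metrics(pm)
  expect_equal(em$mae, 10)
  expect_equal(em$mdape, 7.5)  # median of 10% and 5%
  same <- error_metrics(paired_measurements(c(3, 4), c(3, 4)))
  expect_equal(same$mae, 0)
  expect_equal(same$mdape, 0)
  z <- error_metrics(paired_measurements(c(0, 100), c(5, 110)))
  expect_equal(z$n_excluded_mdape, 1)
  expect_equal(z$mdape, 10)
})

test_that("the agreement report bundles all statistics and tidies to one row each", {
  set.seed(13)
  a <- rnorm(22, 166, 41)
  b <- a + rnorm(22, 4, 9)
  rep <- agreement_report(paired_measurements(a, b), dsc = runif(30, 0.8, 1))
  expect_s3_class(rep, "agreement_report")
  td <- tidy(rep)
  expect_true(all(c("icc_consistency", "icc_absolute", "mae", "mdape",
                    "dsc_mean") %in% td$statistic))
  expect_true(all(is.finite(td$estimate)))
})
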