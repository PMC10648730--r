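# Shared fixtures. Everything is generated in code; the expensive scaled-down
# study (phantom training + application-set evaluation) is memoised so the
# acceptance tests that need it share a single run.

.fixture_env <- new.env(parent = emptyenv())

# a small noise-free phantom used by many I/O and volumetry tests
tiny_phantom <- function(noise_sigma = 0, seed = 1L) {
  key <- paste0("tiny_", noise_sigma, "_", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- generate_phantom(
      phantom_spec_small(noise_sigma = noise_sigma, seed = seed))
  }
  .fixture_env[[key]]
}

# the scaled-down study: 20 training phantoms, 128x64 inputs, 8 starting
# feature maps, 10-phantom application set
study_result <- function() {
  if (is.null(.fixture_env$study)) {
    .fixture_env$study <- run_end_to_end(
      run_config(n_application = 10, seed = 42), verbose = FALSE)
  }
  .fixture_env$study
}

# brute-force volume oracle: iterate every voxel of every mask in the run
brute_force_volume_ml <- function(series, run) {
  if (is.null(run)) return(0)
  total <- 0
  for (i in run[1]:run[2]) {
    m <- if (is.list(series$masks)) series$masks[[i]] else series$masks[, , i]
    cnt <- 0
    for (j in seq_along(m)) if (m[j] != 0) cnt <- cnt + 1
    total <- total + cnt * series$pixel_spacing_x[i] *
      series$pixel_spacing_y[i] * series$slice_z[i]
  }
  total / 1000
}

# exhaustive run-detection oracle: enumerate all maximal runs of consecutive
# slices with count >= floor; longest, then largest pixel sum, then earliest
brute_force_run <- function(counts, floor) {
  n <- length(counts)
  runs <- list()
  i <- 1
  while (i <= n) {
    if (counts[i] >= floor) {
      j <- i
      while (j < n && counts[j + 1] >= floor) j <- j + 1
      runs[[length(runs) + 1]] <- c(i, j)
      i <- j + 1
    } else i <- i + 1
  }
  if (length(runs) == 0) return(NULL)
  best <- NULL; best_len <- -1; best_sum <- -1
  for (r in runs) {
    len <- r[2] - r[1] + 1
    s <- sum(counts[r[1]:r[2]])
    if (len > best_len || (len == best_len && s > best_sum)) {
      best <- r; best_len <- len; best_sum <- s
    }
  }
  best
}

# explicit double-loop two-way ANOVA mean squares (independent ICC oracle)
anova_ms_oracle <- function(x) {
  n <- nrow(x); k <- ncol(x)
  grand <- mean(x)
  ssr <- 0
  for (i in seq_len(n)) ssr <- ssr + k * (mean(x[i, ]) - grand)^2
  ssc <- 0
  for (j in seq_len(k)) ssc <- ssc + n * (mean(x[, j]) - grand)^2
  sse <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(k)) {
      sse <- sse + (x[i, j] - mean(x[i, ]) - mean(x[, j]) + grand)^2
    }
  }
  list(msr = ssr / (n - 1), msc = ssc / (k - 1),
       mse = sse / ((n - 1) * (k - 1)))
}

# spacings are drawn from dyadic rationals (as real CT spacings like 0.625 mm
# are), so every per-slice term and their sum are exactly representable and
# the volume is independent of summation order
random_mask_series <- function(n_slices, h = 12, w = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  masks <- lapply(seq_len(n_slices), function(i) {
    matrix(rbinom(h * w, 1, runif(1, 0, 0.6)), h, w)
  })
  dyadic <- c(0.5, 0.625, 0.75, 1, 1.25, 1.5, 2, 2.5)
  mask_series(masks,
              pixel_spacing_x = sample(dyadic, n_slices, replace = TRUE),
              pixel_spacing_y = sample(dyadic, n_slices, replace = TRUE),
              slice_z = sample(dyadic, n_slices, replace = TRUE))
}
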