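# Slice-to-model-input preprocessing: vertical side split with overlap,
# intensity normalization, resizing, training-set assembly with negative
# controls, and training-time augmentation.

#' Split a transverse slice into per-side halves
#'
#' Splits the image vertically at the center with a configurable overlap:
#' each half extends past the center column by `round(overlap_fraction * W/2)`
#' columns (5\% of the width by default). Under the radiological display
#' convention the patient's right side occupies the low column indices, so the
#' `right` half is `columns[1..W/2+ext]` and the `left` half
#' `columns[W/2-ext+1..W]`.
#'
#' @param slice 2D matrix with an even number of columns.
#' @param overlap_fraction Overlap as a fraction of the full width, in
#'   `[0, 0.5)`; default 0.05.
#' @return A list with `right`, `left` (matrices) and `column_ranges`, a list
#'   of 1-based inclusive `c(start, end)` per side.
#' @examples
#' s <- matrix(rnorm(512 * 512), 512)
#' h <- split_slice(s)
#' ncol(h$right)  # 269 = 256 + round(0.05 * 256)
#' @export
split_slice <- function(slice, overlap_fraction = 0.05) {
  w <- ncol(slice)
  if (w %% 2 != 0) stop("slice width must be even; got ", w)
  if (overlap_fraction < 0 || overlap_fraction >= 0.5) {
    stop("overlap_fraction must be in [0, 0.5)")
  }
  half <- w %/% 2
  ext <- round(overlap_fraction * half)
  r_range <- c(1L, half + ext)
  l_range <- c(half - ext + 1L, w)
  list(right = slice[, r_range[1]:r_range[2], drop = FALSE],
       left = slice[, l_range[1]:l_range[2], drop = FALSE],
       column_ranges = list(right = r_range, left = l_range))
}

#' Reassemble a split slice
#'
#' Inverse of [split_slice()]: the overlap region takes the element-wise
#' maximum of the two halves, so split followed by reassembly is the identity
#' for any overlap fraction.
#'
#' @param halves The list returned by [split_slice()].
#' @return The reconstructed full-width matrix.
#' @export
reassemble_halves <- function(halves) {
  rr <- halves$column_ranges$right
  lr <- halves$column_ranges$left
  w <- lr[2]
  out <- matrix(-Inf, nrow(halves$right), w)
  out[, rr[1]:rr[2]] <- halves$right
  out[, lr[1]:lr[2]] <- pmax(out[, lr[1]:lr[2]], halves$left)
  out
}

resize_bilinear <- function(m, shape) {
  if (all(dim(m) == shape)) return(m)
  as.matrix(EBImage::resize(m, w = shape[1], h = shape[2],
                            filter = "bilinear"))
}

resize_nearest <- function(m, shape) {
  if (all(dim(m) == shape)) return(m)
  out <- as.matrix(EBImage::resize(m, w = shape[1], h = shape[2],
                                   filter = "none"))
  storage.mode(out) <- storage.mode(m)
  out
}

#' Normalize and resize an image or mask
#'
#' Images are min-max normalized to `[0, 1]` (a constant image maps to all
#' zeros) and resized bilinearly; masks are resized with nearest-neighbour
#' interpolation and never intensity-scaled, so they stay strictly binary.
#' A fixed HU window (default -200..300) is available instead of per-image
#' min-max normalization.
#'
#' @param image 2D numeric matrix (finite values).
#' @param target_shape `c(height, width)` of the model input.
#' @param mask Logical; treat the input as a binary mask.
#' @param normalization `"minmax"` (per image) or `"window"` (fixed HU
#'   window).
#' @param window HU window used when `normalization = "window"`.
#' @return A matrix of dimension `target_shape`.
#' @export
normalize_and_resize <- function(image, target_shape, mask = FALSE,
                                 normalization = c("minmax", "window"),
                                 window = c(-200, 300)) {
  normalization <- match.arg(normalization)
  if (mask) {
    m <- resize_nearest(image, target_shape)
    return(matrix(as.integer(m != 0), target_shape[1], target_shape[2]))
  }
  if (!all(is.finite(image))) stop("image contains non-finite values")
  if (normalization == "minmax") {
    rng <- range(image)
    img <- if (rng[2] > rng[1]) (image - rng[1]) / (rng[2] - rng[1])
           else image * 0
  } else {
    img <- pmin(pmax((image - window[1]) / (window[2] - window[1]), 0), 1)
  }
  resize_bilinear(img, target_shape)
}

side_half <- function(slice, side, overlap_fraction) {
  sp <- split_slice(slice, overlap_fraction)
  sp[[side]]
}

#' Assemble per-side training datasets from phantoms
#'
#' Extracts positive slices over each kidney's vertical extent at a fixed
#' table-position interval (10 mm in the clinical protocol), splits them into
#' the side half, normalizes and resizes image and mask identically, and adds
#' side-matching negative-control slices drawn randomly from above and below
#' the kidney. Slices displaying a kidney but lacking a mask are excluded.
#'
#' @param phantoms List of `renalvol_phantom` objects (or a single one).
#' @param side `"left"` or `"right"`.
#' @param target_shape Model input shape `c(height, width)`.
#' @param sampling_interval_mm Vertical sampling interval for positives.
#' @param negative_fraction Fraction of the final dataset made of negative
#'   controls (default 0.28, the ratio of the clinical datasets).
#' @param overlap_fraction Split overlap used for the halves (default 0.05).
#' @param normalization Passed to [normalize_and_resize()].
#' @param seed Integer seed for the negative-control draw.
#' @return An object of class `side_dataset`: a list with `side`, `slices`
#'   (each a `side_slice` with `image`, `mask`, `source_slice_index`,
#'   `source_phantom`, `has_kidney`), and positive/negative counts.
#' @export
build_training_set <- function(phantoms, side = c("right", "left"),
                               target_shape = c(512, 256),
                               sampling_interval_mm = 10,
                               negative_fraction = 0.28,
                               overlap_fraction = 0.05,
                               normalization = "minmax", seed = 1L) {
  side <- match.arg(side)
  if (inherits(phantoms, "renalvol_phantom")) phantoms <- list(phantoms)
  set.seed(seed)
  slices <- list()
  n_pos <- 0L; n_neg <- 0L
  for (pi in seq_along(phantoms)) {
    ph <- phantoms[[pi]]
    vol <- ph$volume
    masks <- ph$truth[[paste0("masks_", side)]]
    counts <- apply(masks, 3, sum)
    pos_slices <- which(counts > 0)
    z <- vol$slice_positions
    if (length(pos_slices) == 0) {
      warning("phantom ", pi, " has no ", side, "-kidney voxels; ",
              "only negatives available")
      chosen <- integer(0)
    } else {
      z0 <- z[min(pos_slices)]; z1 <- z[max(pos_slices)]
      grid <- seq(z0, z1, by = sampling_interval_mm)
      chosen <- unique(vapply(grid, function(g) which.min(abs(z - g)),
                              integer(1)))
      # degenerate extent: always keep at least the central slice
      if (length(chosen) == 0) {
        chosen <- pos_slices[ceiling(length(pos_slices) / 2)]
      }
      chosen <- chosen[counts[chosen] > 0]
      if (length(chosen) == 0) {
        chosen <- pos_slices[ceiling(length(pos_slices) / 2)]
      }
    }
    for (k in chosen) {
      img <- side_half(vol$voxels[, , k], side, overlap_fraction)
      msk <- side_half(masks[, , k], side, overlap_fraction)
      slices[[length(slices) + 1L]] <- structure(list(
        image = normalize_and_resize(img, target_shape,
                                     normalization = normalization),
        mask = normalize_and_resize(msk, target_shape, mask = TRUE),
        side = side, source_slice_index = k, source_phantom = pi,
        has_kidney = TRUE), class = "side_slice")
      n_pos <- n_pos + 1L
    }
    # negative controls: only slices with zero kidney pixels on this side
    neg_pool <- which(counts == 0)
    n_take <- round(length(chosen) * negative_fraction /
                      (1 - negative_fraction))
    n_take <- min(n_take, length(neg_pool))
    if (n_take > 0) {
      for (k in sort(sample(neg_pool, n_take))) {
        img <- side_half(vol$voxels[, , k], side, overlap_fraction)
        slices[[length(slices) + 1L]] <- structure(list(
          image = normalize_and_resize(img, target_shape,
                                       normalization = normalization),
          mask = matrix(0L, target_shape[1], target_shape[2]),
          side = side, source_slice_index = k, source_phantom = pi,
          has_kidney = FALSE), class = "side_slice")
        n_neg <- n_neg + 1L
      }
    }
  }
  if (n_pos == 0) warning("dataset contains no positive slices")
  structure(list(side = side, slices = slices, n_positive = n_pos,
                 n_negative = n_neg, target_shape = target_shape),
            class = "side_dataset")
}

#' @export
print.side_dataset <- function(x, ...) {
  cat(sprintf("%s-kidney dataset: %d slices (%d positive, %d negative), %dx%d\n",
              x$side, length(x$slices), x$n_positive, x$n_negative,
              x$target_shape[1], x$target_shape[2]))
  invisible(x)
}

# radial (barrel / pincushion) distortion with bilinear resampling for the
# image and nearest-neighbour for the mask
optical_distort <- function(image, mask, k) {
  h <- nrow(image); w <- ncol(image)
  u <- (seq_len(h) - (h + 1) / 2) / (h / 2)
  v <- (seq_len(w) - (w + 1) / 2) / (w / 2)
  U <- matrix(u, h, w); V <- matrix(v, h, w, byrow = TRUE)
  r2 <- U^2 + V^2
  f <- 1 + k * r2
  src_i <- U * f * (h / 2) + (h + 1) / 2
  src_j <- V * f * (w / 2) + (w + 1) / 2
  img <- bilinear_sample(image, src_i, src_j)
  msk <- if (is.null(mask)) NULL else nearest_sample(mask, src_i, src_j)
  list(image = img, mask = msk)
}

bilinear_sample <- function(m, si, sj) {
  h <- nrow(m); w <- ncol(m)
  si <- pmin(pmax(si, 1), h); sj <- pmin(pmax(sj, 1), w)
  i0 <- floor(si); j0 <- floor(sj)
  i1 <- pmin(i0 + 1, h); j1 <- pmin(j0 + 1, w)
  di <- si - i0; dj <- sj - j0
  idx <- function(i, j) m[cbind(as.vector(i), as.vector(j))]
  out <- (1 - di) * (1 - dj) * idx(i0, j0) + di * (1 - dj) * idx(i1, j0) +
    (1 - di) * dj * idx(i0, j1) + di * dj * idx(i1, j1)
  matrix(out, h, w)
}

nearest_sample <- function(m, si, sj) {
  h <- nrow(m); w <- ncol(m)
  si <- pmin(pmax(round(si), 1), h); sj <- pmin(pmax(round(sj), 1), w)
  matrix(m[cbind(as.vector(si), as.vector(sj))], h, w)
}

#' Training-time augmentation
#'
#' With probability `probability` applies exactly one transform drawn
#' uniformly from optical distortion, multiplicative noise, and Gaussian
#' blur. The geometric transform (optical distortion) is applied identically
#' to the mask (nearest-neighbour, so it stays binary); the intensity-only
#' transforms leave the mask untouched. Output intensities are clipped to
#' `[0, 1]`.
#'
#' @param image 2D matrix in `[0, 1]`.
#' @param mask Binary 2D matrix or `NULL`.
#' @param probability Augmentation probability (default 0.5).
#' @param distort_limit Maximum absolute radial distortion coefficient.
#' @param noise_range Multiplicative noise factor range.
#' @param blur_sigma_range Gaussian blur sigma range (pixels).
#' @return A list with `image`, `mask`, and `applied` (the transform name or
#'   `"none"`). Uses the current RNG stream; seed outside for reproducibility.
#' @export
augment <- function(image, mask = NULL, probability = 0.5,
                    distort_limit = 0.15, noise_range = c(0.9, 1.1),
                    blur_sigma_range = c(0.5, 1.5)) {
  if (runif(1) >= probability) {
    return(list(image = image, mask = mask, applied = "none"))
  }
  type <- sample(c("optical_distortion", "multiplicative_noise",
                   "gaussian_blur"), 1)
  out <- switch(type,
    optical_distortion = {
      k <- runif(1, -distort_limit, distort_limit)
      optical_distort(image, mask, k)
    },
    multiplicative_noise = {
      f <- matrix(runif(length(image), noise_range[1], noise_range[2]),
                  nrow(image))
      list(image = image * f, mask = mask)
    },
    gaussian_blur = {
      sigma <- runif(1, blur_sigma_range[1], blur_sigma_range[2])
      list(image = as.matrix(EBImage::gblur(image, sigma = sigma)),
           mask = mask)
    })
  list(image = pmin(pmax(out$image, 0), 1), mask = out$mask, applied = type)
}
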