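# Synthetic CT phantoms: two ellipsoidal "kidneys" of soft-tissue attenuation
# embedded in a lower-attenuation fat background, with additive Gaussian noise
# quantized to integer HU (CT stores integer Hounsfield values), realistic
# spacing metadata, and exact analytic ground truth.

#' Specify a synthetic CT phantom
#'
#' Defines the geometry and attenuation of a two-kidney phantom. Patient
#' coordinates follow the radiological display convention: the image column
#' index increases toward the patient's left, so the *left* kidney has the
#' larger x coordinate and appears on the right of the displayed image.
#'
#' Default attenuations emulate unenhanced CT: kidney parenchyma 35 HU inside
#' retroperitoneal fat at -100 HU; `noise_sigma = 20` HU mimics a low-dose
#' acquisition (use ~8 HU for a regular-dose look).
#'
#' @param image_height,image_width Slice matrix size in pixels (512 x 512 in
#'   the clinical protocol; see [phantom_spec_small()] for a fast preset).
#' @param n_slices Number of transverse slices.
#' @param pixel_spacing_x,pixel_spacing_y In-plane pixel spacing in mm
#'   (x = column direction, y = row direction).
#' @param slice_spacing Distance between subsequent slices in mm.
#' @param kidney_semi_axes_left,kidney_semi_axes_right Ellipsoid semi-axes
#'   `(a, b, c)` in mm along x, y, z.
#' @param kidney_center_left,kidney_center_right Ellipsoid centers `(x, y, z)`
#'   in mm. x and y are measured from the slice center; z from the first
#'   slice's table position. Defaults place both kidneys mid-stack.
#' @param kidney_hu,background_hu Attenuation in Hounsfield units.
#' @param noise_sigma Standard deviation of the additive Gaussian noise (HU).
#' @param seed Integer seed; the phantom is a pure function of (spec, seed).
#' @return An object of class `phantom_spec`.
#' @seealso [generate_phantom()], [phantom_spec_small()]
#' @export
phantom_spec <- function(image_height = 512, image_width = 512,
                         n_slices = 160,
                         pixel_spacing_x = 0.75, pixel_spacing_y = 0.75,
                         slice_spacing = 1,
                         kidney_semi_axes_left = c(30, 25, 55),
                         kidney_semi_axes_right = c(28, 24, 52),
                         kidney_center_left = NULL,
                         kidney_center_right = NULL,
                         kidney_hu = 35, background_hu = -100,
                         noise_sigma = 20, seed = 1L) {
  z_mid <- (n_slices - 1) * slice_spacing / 2
  if (is.null(kidney_center_left)) kidney_center_left <- c(55, 0, z_mid)
  if (is.null(kidney_center_right)) kidney_center_right <- c(-55, 0, z_mid)
  spec <- list(image_height = as.integer(image_height),
               image_width = as.integer(image_width),
               n_slices = as.integer(n_slices),
               pixel_spacing_x = pixel_spacing_x,
               pixel_spacing_y = pixel_spacing_y,
               slice_spacing = slice_spacing,
               kidney_semi_axes_left = kidney_semi_axes_left,
               kidney_semi_axes_right = kidney_semi_axes_right,
               kidney_center_left = kidney_center_left,
               kidney_center_right = kidney_center_right,
               kidney_hu = kidney_hu, background_hu = background_hu,
               noise_sigma = noise_sigma, seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

#' Small phantom preset for fast runs
#'
#' A 128 x 128, 36-slice phantom (3 mm pixels, 4 mm slice spacing) whose
#' kidneys have the same analytic volumes as realistic adult kidneys
#' (roughly 120-160 ml). Used by the scaled-down training experiments.
#'
#' @param ... Overrides passed on to [phantom_spec()].
#' @return A `phantom_spec`.
#' @export
phantom_spec_small <- function(...) {
  args <- list(image_height = 128, image_width = 128, n_slices = 36,
               pixel_spacing_x = 3, pixel_spacing_y = 3, slice_spacing = 4,
               kidney_semi_axes_left = c(30, 25, 50),
               kidney_semi_axes_right = c(28, 23, 47),
               kidney_center_left = c(55, 0, 70),
               kidney_center_right = c(-55, 0, 70))
  over <- list(...)
  args[names(over)] <- over
  do.call(phantom_spec, args)
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    stopifnot(image_height > 0, image_width > 0, n_slices > 0,
              pixel_spacing_x > 0, pixel_spacing_y > 0, slice_spacing > 0,
              all(kidney_semi_axes_left > 0), all(kidney_semi_axes_right > 0),
              noise_sigma >= 0)
    if (kidney_center_left[1] <= kidney_center_right[1]) {
      stop("left kidney center x must exceed right kidney center x ",
           "(radiological convention: patient left = larger x)")
    }
    fov_x <- image_width * pixel_spacing_x / 2
    fov_y <- image_height * pixel_spacing_y / 2
    z_max <- (n_slices - 1) * slice_spacing
    for (side in c("left", "right")) {
      ax <- spec[[paste0("kidney_semi_axes_", side)]]
      ce <- spec[[paste0("kidney_center_", side)]]
      if (abs(ce[1]) + ax[1] > fov_x || abs(ce[2]) + ax[2] > fov_y ||
          ce[3] - ax[3] < 0 || ce[3] + ax[3] > z_max) {
        stop(side, " kidney extends outside the field of view: center (",
             paste(signif(ce, 4), collapse = ", "), ") mm, semi-axes (",
             paste(ax, collapse = ", "), ") mm")
      }
    }
  })
  invisible(spec)
}

#' Sample a population of phantom specifications
#'
#' Draws `n` phantoms around a base specification by jittering kidney
#' semi-axes (multiplicatively, +/- `variation`) and centers (by up to
#' `variation` of each semi-axis), emulating anatomical variability between
#' subjects while keeping every kidney inside the field of view.
#'
#' @param n Number of phantoms.
#' @param base A `phantom_spec` to vary around.
#' @param variation Relative variation of the semi-axes (default 0.15).
#' @param seed Integer seed.
#' @return A list of `phantom_spec` objects with distinct seeds.
#' @export
sample_phantom_specs <- function(n, base = phantom_spec_small(),
                                 variation = 0.15, seed = 1L) {
  set.seed(seed)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- unclass(base)
    for (side in c("left", "right")) {
      axf <- paste0("kidney_semi_axes_", side)
      cef <- paste0("kidney_center_", side)
      sp[[axf]] <- sp[[axf]] * runif(3, 1 - variation, 1 + variation)
      sp[[cef]] <- sp[[cef]] + runif(3, -variation, variation) * base[[axf]]
    }
    # keep the kidneys inside the stack in z
    for (side in c("left", "right")) {
      axf <- paste0("kidney_semi_axes_", side)
      cef <- paste0("kidney_center_", side)
      z_max <- (sp$n_slices - 1) * sp$slice_spacing
      sp[[cef]][3] <- min(max(sp[[cef]][3], sp[[axf]][3]), z_max - sp[[axf]][3])
    }
    sp$seed <- base$seed + i
    class(sp) <- "phantom_spec"
    validate_phantom_spec(sp)
    out[[i]] <- sp
  }
  out
}

ellipsoid_mask_slice <- function(spec, side, z) {
  ax <- spec[[paste0("kidney_semi_axes_", side)]]
  ce <- spec[[paste0("kidney_center_", side)]]
  h <- spec$image_height; w <- spec$image_width
  rz <- 1 - ((z - ce[3]) / ax[3])^2
  if (rz <= 0) return(matrix(0L, h, w))
  xs <- (seq_len(w) - (w + 1) / 2) * spec$pixel_spacing_x
  ys <- (seq_len(h) - (h + 1) / 2) * spec$pixel_spacing_y
  # voxel belongs to the ellipsoid iff its center is inside
  fx <- ((xs - ce[1]) / ax[1])^2
  fy <- ((ys - ce[2]) / ax[2])^2
  m <- outer(fy, fx, "+") <= rz
  mode(m) <- "integer"
  m
}

#' Generate a synthetic CT phantom
#'
#' Voxels take the kidney attenuation inside either ellipsoid and the
#' background attenuation elsewhere; i.i.d. Gaussian noise of sd
#' `noise_sigma` is added and the result is rounded to integer HU, as a CT
#' scanner would store it. Ground-truth masks are the exact noise-free
#' ellipsoid interiors (a voxel is inside iff its center is), so the
#' voxel-count volume converges to the analytic ellipsoid volume
#' \eqn{4/3 \pi a b c} as the spacing is refined. Slices with no kidney
#' voxels remain above and below each kidney as negative controls.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `renalvol_phantom` with elements `volume` (a
#'   [ct_volume()]) and `truth` (class `ground_truth`: `masks_left`,
#'   `masks_right` as H x W x S binary arrays and `analytic_volume_left/right`
#'   in ml).
#' @examples
#' ph <- generate_phantom(phantom_spec_small(noise_sigma = 0))
#' ph$truth$analytic_volume_left  # 4/3*pi*30*25*50 / 1000 ml
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)
  h <- spec$image_height; w <- spec$image_width; s <- spec$n_slices
  zs <- (seq_len(s) - 1) * spec$slice_spacing
  ml <- array(0L, c(h, w, s))
  mr <- array(0L, c(h, w, s))
  vox <- array(spec$background_hu, c(h, w, s))
  for (k in seq_len(s)) {
    ml[, , k] <- ellipsoid_mask_slice(spec, "left", zs[k])
    mr[, , k] <- ellipsoid_mask_slice(spec, "right", zs[k])
    sl <- vox[, , k]
    sl[ml[, , k] == 1L | mr[, , k] == 1L] <- spec$kidney_hu
    vox[, , k] <- sl
  }
  if (spec$noise_sigma > 0) {
    set.seed(spec$seed)
    vox <- vox + rnorm(length(vox), sd = spec$noise_sigma)
    vox <- round(vox)
  }
  vol <- ct_volume(vox,
                   pixel_spacing = c(spec$pixel_spacing_x,
                                     spec$pixel_spacing_y),
                   slice_positions = zs)
  axl <- spec$kidney_semi_axes_left
  axr <- spec$kidney_semi_axes_right
  truth <- structure(list(
    masks_left = ml, masks_right = mr,
    analytic_volume_left = 4 / 3 * pi * prod(axl) / 1000,
    analytic_volume_right = 4 / 3 * pi * prod(axr) / 1000,
    spec = spec), class = "ground_truth")
  structure(list(volume = vol, truth = truth), class = "renalvol_phantom")
}

#' @export
print.renalvol_phantom <- function(x, ...) {
  cat(sprintf(
    "CT phantom: %dx%dx%d voxels, analytic volumes L %.1f ml / R %.1f ml\n",
    dim(x$volume$voxels)[1], dim(x$volume$voxels)[2],
    dim(x$volume$voxels)[3],
    x$truth$analytic_volume_left, x$truth$analytic_volume_right))
  invisible(x)
}

#' Ground-truth mask series for one side
#'
#' Convenience accessor turning a phantom's ground truth into the
#' [mask_series()] consumed by the volumetry functions.
#'
#' @param phantom A `renalvol_phantom`.
#' @param side `"left"` or `"right"`.
#' @return A `mask_series`.
#' @export
truth_mask_series <- function(phantom, side = c("left", "right")) {
  side <- match.arg(side)
  m <- phantom$truth[[paste0("masks_", side)]]
  vol <- phantom$volume
  mask_series(m, pixel_spacing_x = vol$pixel_spacing_x,
              pixel_spacing_y = vol$pixel_spacing_y,
              slice_z = slice_z_spacing(vol), side = side)
}
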