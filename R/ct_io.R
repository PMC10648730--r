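# CT volume container and I/O: NIfTI volumes via RNifti, DICOM series via the
# minimal reader/writer in dicom.R, 2D masks as PNG or NIfTI.

#' Construct a CT volume
#'
#' The in-memory representation of a CT series: a 3D voxel array (row, column,
#' slice; slices ordered by table position) plus per-slice spacing metadata.
#' Pixel spacings may vary per slice, matching what DICOM headers allow.
#'
#' @param voxels 3D numeric array (height x width x n_slices) of attenuation
#'   values in HU.
#' @param pixel_spacing Either `c(x, y)` in mm applied to all slices or an
#'   n_slices x 2 matrix of per-slice (x, y) spacings.
#' @param slice_positions Table positions in mm, one per slice, strictly
#'   monotone. Defaults to `(0:(n-1)) * slice_spacing`.
#' @param slice_spacing Nominal inter-slice distance in mm (used when
#'   `slice_positions` is absent, and as the spacing of a single-slice
#'   volume).
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, pixel_spacing, slice_positions = NULL,
                      slice_spacing = NULL) {
  stopifnot(length(dim(voxels)) == 3)
  s <- dim(voxels)[3]
  if (is.matrix(pixel_spacing)) {
    stopifnot(nrow(pixel_spacing) == s, ncol(pixel_spacing) == 2)
    psx <- pixel_spacing[, 1]; psy <- pixel_spacing[, 2]
  } else {
    stopifnot(length(pixel_spacing) == 2)
    psx <- rep(pixel_spacing[1], s); psy <- rep(pixel_spacing[2], s)
  }
  if (is.null(slice_positions)) {
    if (is.null(slice_spacing)) {
      stop("either slice_positions or slice_spacing is required")
    }
    slice_positions <- (seq_len(s) - 1) * slice_spacing
  }
  stopifnot(length(slice_positions) == s, all(psx > 0), all(psy > 0))
  if (s > 1 && any(diff(slice_positions) <= 0)) {
    stop("slice_positions must be strictly increasing")
  }
  if (is.null(slice_spacing)) {
    slice_spacing <- if (s > 1) diff(slice_positions)[1] else NA_real_
  }
  structure(list(voxels = voxels, pixel_spacing_x = psx,
                 pixel_spacing_y = psy, slice_positions = slice_positions,
                 slice_spacing = slice_spacing),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("CT volume: %d slices of %dx%d, pixel spacing %gx%g mm, %s\n",
              d[3], d[1], d[2], x$pixel_spacing_x[1], x$pixel_spacing_y[1],
              if (d[3] > 1) {
                g <- diff(x$slice_positions)
                if (max(g) - min(g) < 1e-9) sprintf("slice spacing %g mm", g[1])
                else sprintf("non-uniform slice spacing %g-%g mm",
                             min(g), max(g))
              } else sprintf("single slice (spacing %g mm)", x$slice_spacing)))
  invisible(x)
}

#' Per-slice inter-slice distance
#'
#' The distance between subsequent slices, one value per slice (the gap to the
#' following slice; the last slice reuses the final gap). This is the `z`
#' factor of the voxel-summation volume formula and supports non-uniform
#' stacks.
#'
#' @param vol A `ct_volume`.
#' @return Numeric vector, one value per slice.
#' @export
slice_z_spacing <- function(vol) {
  n <- length(vol$slice_positions)
  if (n == 1) {
    if (is.na(vol$slice_spacing)) {
      stop("single-slice volume without an explicit slice spacing")
    }
    return(vol$slice_spacing)
  }
  g <- diff(vol$slice_positions)
  c(g, g[n - 1])
}

#' Write a CT volume to disk
#'
#' @param vol A [ct_volume()].
#' @param path Output file (NIfTI) or directory (DICOM series, one file per
#'   slice).
#' @param format `"nifti"` or `"dicom_series"`.
#' @return `path`, invisibly.
#' @details The NIfTI writer stores voxels as float64 with spacings in
#'   `pixdim` and requires uniform spacing; the DICOM writer emits one
#'   explicit-VR little-endian file per slice carrying `PixelSpacing`,
#'   `SpacingBetweenSlices`, `ImagePositionPatient` and `InstanceNumber`, and
#'   stores voxels as signed 16-bit integers (integer HU).
#' @export
write_volume <- function(vol, path, format = c("nifti", "dicom_series")) {
  stopifnot(inherits(vol, "ct_volume"))
  format <- match.arg(format)
  if (format == "nifti") {
    g <- if (length(vol$slice_positions) > 1) diff(vol$slice_positions)
         else vol$slice_spacing
    if (max(g) - min(g) > 1e-9) {
      stop("NIfTI cannot represent non-uniform slice spacing; ",
           "use format = \"dicom_series\"")
    }
    if (max(vol$pixel_spacing_x) - min(vol$pixel_spacing_x) > 1e-12 ||
        max(vol$pixel_spacing_y) - min(vol$pixel_spacing_y) > 1e-12) {
      stop("NIfTI cannot represent per-slice pixel spacing")
    }
    img <- RNifti::asNifti(
      vol$voxels,
      reference = list(pixdim = c(-1, vol$pixel_spacing_y[1],
                                  vol$pixel_spacing_x[1], g[1], 0, 0, 0, 0)),
      datatype = "double")
    RNifti::writeNifti(img, path)
  } else {
    write_dicom_series(vol, path)
  }
  invisible(path)
}

#' Read a CT series into a `ct_volume`
#'
#' Accepts either a DICOM series directory (one file per slice) or a NIfTI
#' file. DICOM slices are sorted by their table position (`z` component of
#' `ImagePositionPatient`), falling back to `InstanceNumber`, so the result
#' is independent of on-disk file order. Inter-slice distances are computed
#' from consecutive positions and kept per gap; a warning is raised (and the
#' per-gap distances retained) when the gaps are non-uniform beyond
#' `tolerance`. `RescaleSlope`/`RescaleIntercept` are applied.
#'
#' @param path Directory containing a single DICOM series, or a NIfTI file.
#' @param tolerance Relative tolerance for declaring slice gaps uniform.
#' @return A [ct_volume()].
#' @export
read_series <- function(path, tolerance = 1e-3) {
  if (dir.exists(path)) {
    return(read_dicom_series(path, tolerance = tolerance))
  }
  if (!file.exists(path)) stop("no such file or directory: ", path)
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  arr <- as.array(img)
  if (length(dim(arr)) != 3) stop("expected a 3D NIfTI volume")
  ct_volume(arr, pixel_spacing = c(pd[2], pd[1]),
            slice_positions = (seq_len(dim(arr)[3]) - 1) * pd[3],
            slice_spacing = pd[3])
}

#' Read a 2D binary mask
#'
#' Reads a PNG or NIfTI mask and binarizes it: any nonzero pixel becomes 1
#' (masks are conceptually binary; 8-bit exports may store foreground as 255).
#'
#' @param path PNG or NIfTI file.
#' @return Integer 0/1 matrix.
#' @export
read_mask <- function(path) {
  m <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    p <- png::readPNG(path)
    if (length(dim(p)) == 3) p <- p[, , 1]
    p
  } else {
    as.array(RNifti::readNifti(path))
  }
  if (length(dim(m)) != 2) stop("mask must be 2D; got ",
                                length(dim(m)), " dimensions")
  out <- matrix(as.integer(m != 0), nrow(m), ncol(m))
  out
}

#' Write a 2D binary mask
#'
#' @param mask 2D array; any nonzero value is foreground.
#' @param path Output file; `.png` or `.nii`/`.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  if (length(dim(mask)) != 2) stop("mask must be 2D")
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(matrix(as.numeric(m), nrow(m), ncol(m)), path)
  } else {
    RNifti::writeNifti(RNifti::asNifti(m, datatype = "uint8"), path)
  }
  invisible(path)
}
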