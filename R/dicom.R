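# Minimal DICOM series writer/reader: explicit-VR little-endian, single-frame
# CT images, one file per slice. Covers exactly the metadata the volumetry
# needs (PixelSpacing, SpacingBetweenSlices, ImagePositionPatient,
# InstanceNumber, Rescale*), with voxels stored as signed 16-bit integer HU.
# Not a general DICOM implementation: compressed transfer syntaxes, implicit
# VR and sequences are out of scope.

DCM_UID_ROOT <- "1.2.826.0.1.3680043.10.1465."
UID_CT_STORAGE <- "1.2.840.10008.5.1.4.1.1.2"
UID_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

dcm_write_element <- function(con, group, element, vr, value) {
  writeBin(as.integer(c(group, element)), con, size = 2, endian = "little")
  writeChar(vr, con, nchars = 2, eos = NULL)
  if (vr %in% c("OB", "OW")) {
    writeBin(as.integer(0), con, size = 2, endian = "little")  # reserved
    writeBin(length(value), con, size = 4, endian = "little")
    writeBin(value, con)
  } else if (vr %in% c("US", "UL")) {
    n <- length(value)
    size <- if (vr == "US") 2L else 4L
    writeBin(as.integer(n * size), con, size = 2, endian = "little")
    writeBin(as.integer(value), con, size = size, endian = "little")
  } else {
    # values padded to even length: UIDs with a NUL byte, text with a space
    odd <- nchar(value) %% 2 == 1
    if (odd && vr != "UI") value <- paste0(value, " ")
    len <- nchar(value) + (odd && vr == "UI")
    writeBin(as.integer(len), con, size = 2, endian = "little")
    writeChar(value, con, nchars = nchar(value), eos = NULL)
    if (odd && vr == "UI") writeBin(raw(1), con)
  }
}

ds_fmt <- function(x) {
  paste(vapply(x, function(v) sprintf("%.10g", v), character(1)),
        collapse = "\\")
}

write_dicom_slice <- function(path, slice, psx, psy, z, instance,
                              slice_spacing, series_uid, sop_uid) {
  px <- as.integer(round(t(slice)))  # DICOM pixel data is row-major
  if (any(px < -32768 | px > 32767)) {
    stop("voxel values outside the signed 16-bit range")
  }
  # file meta group, buffered so its group length can be computed
  meta <- rawConnection(raw(0), "w")
  dcm_write_element(meta, 0x0002, 0x0001, "OB", as.raw(c(0, 1)))
  dcm_write_element(meta, 0x0002, 0x0002, "UI", UID_CT_STORAGE)
  dcm_write_element(meta, 0x0002, 0x0003, "UI", sop_uid)
  dcm_write_element(meta, 0x0002, 0x0010, "UI", UID_EXPLICIT_LE)
  meta_raw <- rawConnectionValue(meta)
  close(meta)

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeChar("DICM", con, nchars = 4, eos = NULL)
  dcm_write_element(con, 0x0002, 0x0000, "UL", length(meta_raw))
  writeBin(meta_raw, con)
  dcm_write_element(con, 0x0008, 0x0016, "UI", UID_CT_STORAGE)
  dcm_write_element(con, 0x0008, 0x0018, "UI", sop_uid)
  dcm_write_element(con, 0x0008, 0x0060, "CS", "CT")
  dcm_write_element(con, 0x0018, 0x0050, "DS", ds_fmt(slice_spacing))
  dcm_write_element(con, 0x0018, 0x0088, "DS", ds_fmt(slice_spacing))
  dcm_write_element(con, 0x0020, 0x000D, "UI", paste0(DCM_UID_ROOT, "1"))
  dcm_write_element(con, 0x0020, 0x000E, "UI", series_uid)
  dcm_write_element(con, 0x0020, 0x0013, "IS", as.character(instance))
  dcm_write_element(con, 0x0020, 0x0032, "DS", ds_fmt(c(0, 0, z)))
  dcm_write_element(con, 0x0020, 0x0037, "DS", ds_fmt(c(1, 0, 0, 0, 1, 0)))
  dcm_write_element(con, 0x0028, 0x0002, "US", 1)
  dcm_write_element(con, 0x0028, 0x0004, "CS", "MONOCHROME2")
  dcm_write_element(con, 0x0028, 0x0010, "US", nrow(slice))
  dcm_write_element(con, 0x0028, 0x0011, "US", ncol(slice))
  # PixelSpacing is (row spacing, column spacing) = (y, x)
  dcm_write_element(con, 0x0028, 0x0030, "DS", ds_fmt(c(psy, psx)))
  dcm_write_element(con, 0x0028, 0x0100, "US", 16)
  dcm_write_element(con, 0x0028, 0x0101, "US", 16)
  dcm_write_element(con, 0x0028, 0x0102, "US", 15)
  dcm_write_element(con, 0x0028, 0x0103, "US", 1)
  dcm_write_element(con, 0x0028, 0x1052, "DS", "0")
  dcm_write_element(con, 0x0028, 0x1053, "DS", "1")
  pd <- writeBin(px, raw(), size = 2, endian = "little")
  dcm_write_element(con, 0x7FE0, 0x0010, "OW", pd)
  invisible(path)
}

write_dicom_series <- function(vol, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  vox <- vol$voxels
  if (max(abs(vox - round(vox))) > 1e-9) {
    stop("DICOM output stores integer HU; volume has non-integer voxels")
  }
  s <- dim(vox)[3]
  zspace <- slice_z_spacing(vol)
  series_uid <- paste0(DCM_UID_ROOT, "2.1")
  for (k in seq_len(s)) {
    write_dicom_slice(
      file.path(dir, sprintf("slice_%04d.dcm", k)),
      vox[, , k], vol$pixel_spacing_x[k], vol$pixel_spacing_y[k],
      vol$slice_positions[k], k, zspace[min(k, length(zspace))],
      series_uid, paste0(DCM_UID_ROOT, "2.1.", k))
  }
  invisible(dir)
}

read_dicom_file <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM") {
    stop(path, " is not a DICOM file (missing DICM magic)")
  }
  pos <- 133L
  u16 <- function(i) as.integer(raw[i]) + 256L * as.integer(raw[i + 1L])
  u32 <- function(i) u16(i) + 65536 * u16(i + 2L)
  out <- list()
  while (pos + 8L <= length(raw)) {
    group <- u16(pos); element <- u16(pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr)) {
      stop(path, ": implicit-VR or corrupt element at offset ", pos,
           " (only explicit-VR little endian is supported)")
    }
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      len <- u32(pos + 8L)
      vstart <- pos + 12L
    } else {
      len <- u16(pos + 6L)
      vstart <- pos + 8L
    }
    val <- raw[vstart:(vstart + len - 1L)]
    key <- sprintf("%04x,%04x", group, element)
    txt <- function() sub(" +$", "", rawToChar(val[val != as.raw(0)]))
    nums <- function() as.numeric(strsplit(txt(), "\\\\")[[1]])
    switch(key,
      "0018,0088" = out$spacing_between <- nums(),
      "0020,0013" = out$instance <- as.integer(txt()),
      "0020,0032" = out$position <- nums(),
      "0028,0010" = out$rows <- u16(vstart),
      "0028,0011" = out$cols <- u16(vstart),
      "0028,0030" = out$pixel_spacing <- nums(),
      "0028,0100" = out$bits <- u16(vstart),
      "0028,0103" = out$signed <- u16(vstart),
      "0028,1052" = out$intercept <- nums(),
      "0028,1053" = out$slope <- nums(),
      "7fe0,0010" = out$pixel_raw <- val
    )
    pos <- vstart + len
    if (len %% 2L == 1L) pos <- pos + 1L
  }
  if (is.null(out$rows) || is.null(out$pixel_raw)) {
    stop(path, ": no image data found")
  }
  if (!identical(out$bits, 16L)) stop(path, ": only 16-bit pixels supported")
  v <- readBin(out$pixel_raw, "integer", n = out$rows * out$cols,
               size = 2, signed = TRUE, endian = "little")
  slope <- if (is.null(out$slope)) 1 else out$slope
  intercept <- if (is.null(out$intercept)) 0 else out$intercept
  out$slice <- matrix(v * slope + intercept, out$rows, out$cols, byrow = TRUE)
  out
}

read_dicom_series <- function(dir, tolerance = 1e-3) {
  files <- list.files(dir, pattern = "\\.dcm$", full.names = TRUE,
                      ignore.case = TRUE)
  if (length(files) == 0) {
    files <- list.files(dir, full.names = TRUE)
    files <- files[!dir.exists(files)]
  }
  if (length(files) == 0) stop("no DICOM files in ", dir)
  slices <- lapply(files, read_dicom_file)
  dims <- vapply(slices, function(s) c(s$rows, s$cols), numeric(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("mixed matrix sizes in ", dir,
         ": a single coherent series is required")
  }
  zs <- vapply(slices, function(s) {
    if (!is.null(s$position)) s$position[3] else NA_real_
  }, numeric(1))
  if (anyNA(zs)) {
    inst <- vapply(slices, function(s) {
      if (is.null(s$instance)) NA_integer_ else s$instance
    }, integer(1))
    if (anyNA(inst)) {
      stop("slices carry neither ImagePositionPatient nor InstanceNumber")
    }
    ord <- order(inst)
    zs <- (seq_along(slices) - 1) *
      (slices[[1]]$spacing_between %||% 1)
  } else {
    ord <- order(zs)
    zs <- zs[ord]
  }
  slices <- slices[ord]
  n <- length(slices)
  vox <- array(0, c(slices[[1]]$rows, slices[[1]]$cols, n))
  ps <- matrix(0, n, 2)
  for (k in seq_len(n)) {
    vox[, , k] <- slices[[k]]$slice
    # PixelSpacing tag order is (row = y, column = x); ct_volume wants (x, y)
    ps[k, ] <- rev(slices[[k]]$pixel_spacing)
  }
  explicit_spacing <- slices[[1]]$spacing_between
  if (n == 1) {
    if (is.null(explicit_spacing)) {
      stop("single-slice series without a SpacingBetweenSlices tag")
    }
    return(ct_volume(vox, pixel_spacing = ps, slice_positions = zs,
                     slice_spacing = explicit_spacing))
  }
  gaps <- diff(zs)
  if ((max(gaps) - min(gaps)) / mean(gaps) > tolerance) {
    warning("non-uniform inter-slice gaps (", signif(min(gaps), 4), "-",
            signif(max(gaps), 4), " mm); per-gap distances retained")
  }
  ct_volume(vox, pixel_spacing = ps, slice_positions = zs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
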