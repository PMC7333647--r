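# Minimal NIfTI-1 I/O.
#
# The pipeline exchanges volumes as single-file NIfTI-1 (.nii or .nii.gz).
# No NIfTI package ships with the target environment, so a small, strict
# reader/writer for the subset we emit (3D, little-endian, sform-only
# orientation) is implemented here. It is not a general NIfTI library.

#' Create an image volume
#'
#' A light container for a 3D scalar grid plus voxel spacing in mm. This is
#' the lattice all transforms operate on; masks are plain logical/0-1 arrays
#' on the same lattice.
#'
#' @param values numeric 3D array.
#' @param spacing numeric length-3 voxel spacing in mm, all > 0.
#' @return an object of class `image_volume` with fields `values`, `spacing`.
#' @export
image_volume <- function(values, spacing = c(1, 1, 1)) {
  if (length(dim(values)) != 3L) stop_cfg("values must be a 3D array")
  if (!all(is.finite(values))) stop_cfg("values must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop_cfg("spacing must be 3 positive numbers (mm)")
  }
  structure(list(values = values, spacing = spacing), class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume> ", paste(dim(x$values), collapse = " x "),
      " voxels, spacing ", paste(format(x$spacing), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

as_volume_array <- function(x) {
  if (inherits(x, "image_volume")) x$values else x
}

vol_spacing <- function(x, default = c(1, 1, 1)) {
  if (inherits(x, "image_volume")) x$spacing else default
}

nifti_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Write a 3D volume as NIfTI-1
#'
#' Writes a single-file little-endian NIfTI-1 image (float32 by default,
#' uint8 for masks), with voxel spacing carried in `pixdim` and a diagonal
#' sform. `.nii.gz` paths are gzip-compressed transparently.
#'
#' @param vol an [image_volume()] or 3D array.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param spacing voxel spacing (mm); ignored when `vol` is an `image_volume`.
#' @param datatype `"float32"` or `"uint8"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(vol, path, spacing = c(1, 1, 1),
                        datatype = c("float32", "uint8")) {
  datatype <- match.arg(datatype)
  arr <- as_volume_array(vol)
  spacing <- vol_spacing(vol, spacing)
  if (length(dim(arr)) != 3L) stop_cfg("write_nifti expects a 3D array")
  dt_code <- c(float32 = 16L, uint8 = 2L)[[datatype]]
  bitpix <- c(float32 = 32L, uint8 = 8L)[[datatype]]

  con <- nifti_connection(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wc <- function(s, n) {
    raw <- charToRaw(s)
    writeBin(c(raw, raw(n - length(raw))), con)
  }

  wi(348L, 4)                      # sizeof_hdr
  wc("", 10); wc("", 18)           # data_type, db_name (unused)
  wi(0L, 4); wi(0L, 2); wc("r", 1); wc("", 1)  # extents, session_error, regular, dim_info
  wi(c(3L, dim(arr), 1L, 1L, 1L, 1L), 2)       # dim[8]
  wf(c(0, 0, 0)); wi(0L, 2)        # intent_p1-3, intent_code
  wi(dt_code, 2); wi(bitpix, 2); wi(0L, 2)     # datatype, bitpix, slice_start
  wf(c(1, spacing, 0, 0, 0, 0))    # pixdim[8]
  wf(352); wf(1); wf(0)            # vox_offset, scl_slope, scl_inter
  wi(0L, 2); wc("", 1)             # slice_end, slice_code
  writeBin(as.raw(2L), con)        # xyzt_units: mm
  wf(c(0, 0, 0, 0))                # cal_max, cal_min, slice_duration, toffset
  wi(c(0L, 0L), 4)                 # glmax, glmin
  wc("cicradiomics synthetic volume", 80)      # descrip
  wc("", 24)                       # aux_file
  wi(0L, 2); wi(1L, 2)             # qform_code, sform_code
  wf(c(0, 0, 0)); wf(c(0, 0, 0))   # quatern_b-d, qoffset_x-z
  wf(c(spacing[1], 0, 0, 0))       # srow_x
  wf(c(0, spacing[2], 0, 0))       # srow_y
  wf(c(0, 0, spacing[3], 0))       # srow_z
  wc("", 16)                       # intent_name
  wc("n+1", 4)                     # magic
  writeBin(raw(4), con)            # extension flag

  vals <- as.vector(arr)
  if (datatype == "uint8") {
    writeBin(as.raw(pmin(pmax(round(vals), 0), 255)), con)
  } else {
    writeBin(as.numeric(vals), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' Strict reader for the single-file little-endian subset written by
#' [write_nifti()] (plus int16/int32/float64 payloads for robustness).
#' Applies `scl_slope`/`scl_inter` when set.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return an [image_volume()].
#' @export
read_nifti <- function(path) {
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 352)
  if (length(hdr) < 348) stop_data("truncated NIfTI header in ", path)
  ri <- function(off, size, n = 1L) {
    readBin(hdr[(off + 1L):(off + size * n)], "integer", n = n, size = size,
            endian = "little", signed = size > 1)
  }
  rf <- function(off, n = 1L) {
    readBin(hdr[(off + 1L):(off + 4L * n)], "double", n = n, size = 4,
            endian = "little")
  }
  if (ri(0, 4) != 348L) stop_data("not a little-endian NIfTI-1 file: ", path)
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop_data("bad NIfTI magic in ", path)
  dims <- ri(40, 2, 8L)
  if (dims[1] < 3L) stop_data("expected a 3D NIfTI volume in ", path)
  nx <- dims[2]; ny <- dims[3]; nz <- dims[4]
  nt <- max(1L, dims[5])
  if (nt != 1L) stop_data("4D NIfTI not supported: ", path)
  dt <- ri(70, 2)
  pixdim <- rf(76, 8L)
  vox_offset <- rf(108)
  slope <- rf(112); inter <- rf(116)
  if (vox_offset > 352) readBin(con, "raw", n = vox_offset - 352)
  nvox <- nx * ny * nz
  vals <- switch(as.character(dt),
    "2"  = as.numeric(as.integer(readBin(con, "raw", n = nvox))),
    "4"  = readBin(con, "integer", n = nvox, size = 2, endian = "little"),
    "8"  = readBin(con, "integer", n = nvox, size = 4, endian = "little"),
    "16" = readBin(con, "double", n = nvox, size = 4, endian = "little"),
    "64" = readBin(con, "double", n = nvox, size = 8, endian = "little"),
    stop_data("unsupported NIfTI datatype code ", dt, " in ", path))
  if (length(vals) < nvox) stop_data("truncated NIfTI data in ", path)
  vals <- as.numeric(vals)
  if (is.finite(slope) && slope != 0 && !(slope == 1 && inter == 0)) {
    vals <- vals * slope + inter
  }
  image_volume(array(vals, dim = c(nx, ny, nz)), spacing = pixdim[2:4])
}
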