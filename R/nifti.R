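# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
#
# No NIfTI package is available in the target library, so the format is
# handled here directly. Scope is deliberately narrow: single-file NIfTI-1
# ("n+1" magic), datatypes uint8/int16/int32/uint16/float32/float64, spacing
# from pixdim, scl_slope/scl_inter honoured on read. Orientation is recorded
# as a diagonal sform on write and ignored on read: all package computations
# are intra-grid (voxel indices scaled by spacing).

NIFTI_DT <- list(uint8 = 2L, int16 = 4L, int32 = 8L, float32 = 16L,
                 float64 = 64L, uint16 = 512L)
NIFTI_BITPIX <- c(`2` = 8L, `4` = 16L, `8` = 32L, `16` = 32L, `64` = 64L, `512` = 16L)

nifti_open <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

# Parse a raw NIfTI-1 header (348 bytes) into the fields we use.
parse_nifti_header <- function(hdr_raw) {
  rd <- function(what, n, size, offset, endian, signed = TRUE) {
    readBin(hdr_raw[(offset + 1):length(hdr_raw)], what, n = n, size = size,
            endian = endian, signed = signed)
  }
  endian <- "little"
  sizeof_hdr <- rd(integer(), 1L, 4L, 0L, endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sizeof_hdr <- rd(integer(), 1L, 4L, 0L, endian)
    if (sizeof_hdr != 348L) stop_mdaqp("not a NIfTI-1 file (sizeof_hdr != 348)")
  }
  dim <- rd(integer(), 8L, 2L, 40L, endian)
  datatype <- rd(integer(), 1L, 2L, 70L, endian)
  pixdim <- rd(numeric(), 8L, 4L, 76L, endian)
  vox_offset <- rd(numeric(), 1L, 4L, 108L, endian)
  scl_slope <- rd(numeric(), 1L, 4L, 112L, endian)
  scl_inter <- rd(numeric(), 1L, 4L, 116L, endian)
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop_mdaqp("not a NIfTI-1 file (bad magic '%s')", magic)
  list(endian = endian, dim = dim, datatype = datatype, pixdim = pixdim,
       vox_offset = vox_offset, scl_slope = scl_slope, scl_inter = scl_inter)
}

read_nifti_raw <- function(path) {
  if (!file.exists(path)) stop_mdaqp("file not found: %s", path)
  con <- nifti_open(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, raw(), n = 348L)
  if (length(hdr_raw) < 348L) stop_mdaqp("truncated NIfTI header in %s", path)
  h <- parse_nifti_header(hdr_raw)
  ndim <- h$dim[1L]
  if (ndim < 1L || ndim > 7L) stop_mdaqp("invalid NIfTI dim[0] = %d", ndim)
  shape <- h$dim[2L:(1L + ndim)]
  n <- prod(shape)
  skip <- max(0, round(h$vox_offset) - 348L)
  if (skip > 0) readBin(con, raw(), n = skip)
  dt <- h$datatype
  vals <- switch(as.character(dt),
    "2"   = readBin(con, integer(), n = n, size = 1L, endian = h$endian, signed = FALSE),
    "4"   = readBin(con, integer(), n = n, size = 2L, endian = h$endian, signed = TRUE),
    "8"   = readBin(con, integer(), n = n, size = 4L, endian = h$endian),
    "16"  = readBin(con, numeric(), n = n, size = 4L, endian = h$endian),
    "64"  = readBin(con, numeric(), n = n, size = 8L, endian = h$endian),
    "512" = readBin(con, integer(), n = n, size = 2L, endian = h$endian, signed = FALSE),
    stop_mdaqp("unsupported NIfTI datatype code %d", dt))
  if (length(vals) < n) stop_mdaqp("truncated NIfTI data in %s", path)
  if (is.finite(h$scl_slope) && h$scl_slope != 0 &&
      !(h$scl_slope == 1 && h$scl_inter == 0))
    vals <- vals * h$scl_slope + h$scl_inter
  list(data = array(vals, dim = shape), spacing_mm = abs(h$pixdim[2L:4L]), ndim = ndim)
}

#' Read a 3D NIfTI-1 volume
#'
#' Reads a single-file NIfTI-1 volume (`.nii` or `.nii.gz`) into an
#' [image_volume]. Voxel spacing is taken from `pixdim`; `scl_slope` /
#' `scl_inter` are applied. The affine rotation is ignored — the package works
#' in voxel space throughout.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param kind `"scalar"` (default), `"mask"` or `"label"`; masks are
#'   binarised with `> 0`.
#' @return An [image_volume]. Scalar volumes containing NaN/Inf raise a
#'   validation error reporting the offending voxel count.
#' @export
read_nifti <- function(path, kind = c("scalar", "mask", "label")) {
  kind <- match.arg(kind)
  raw <- read_nifti_raw(path)
  if (raw$ndim != 3L)
    stop_mdaqp("expected a 3D volume, got %dD in %s", raw$ndim, path)
  data <- raw$data
  if (kind == "mask") data <- data > 0
  if (kind == "label") storage.mode(data) <- "integer"
  image_volume(data, spacing_mm = raw$spacing_mm, kind = kind)
}

#' Write a volume as NIfTI-1
#'
#' Writes a single-file little-endian NIfTI-1 (`.nii` or `.nii.gz`, chosen by
#' extension). Scalar data are stored as float64 so round trips are bit-exact;
#' masks as uint8; labels as int32. A diagonal sform carries the spacing.
#'
#' @param vol an [image_volume], or a 3D array (spacing then required).
#' @param path output path.
#' @param spacing_mm spacing override when `vol` is a bare array.
#' @return Invisibly, `path`.
#' @export
write_nifti <- function(vol, path, spacing_mm = NULL) {
  if (!inherits(vol, "image_volume")) {
    stopifnot(is.array(vol))
    vol <- image_volume(if (is.logical(vol)) vol else vol,
                        spacing_mm = spacing_mm %||% c(1, 1, 1),
                        kind = if (is.logical(vol)) "mask" else "scalar")
  }
  data <- vol$data
  dtname <- if (is.logical(data)) "uint8"
            else if (vol$kind == "label" || is.integer(data)) "int32"
            else "float64"
  dt <- NIFTI_DT[[dtname]]
  write_nifti_array(data, vol$spacing_mm, path, dt)
  invisible(path)
}

# Core writer; `data` may be 3D or 4D.
write_nifti_array <- function(data, spacing_mm, path, dt = 64L) {
  dims <- dim(data)
  ndim <- length(dims)
  con <- nifti_open(path, "wb")
  on.exit(close(con))
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w_f32 <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)

  w_i32(348L)                       # sizeof_hdr
  w_raw(36L)                        # data_type..dim_info
  dimfield <- c(ndim, dims, rep(1L, 7L - ndim))
  w_i16(dimfield)                   # dim[8]
  w_raw(14L)                        # intent_p1..intent_code
  w_i16(dt)                         # datatype
  w_i16(NIFTI_BITPIX[[as.character(dt)]])  # bitpix
  w_i16(0L)                         # slice_start
  pixdim <- c(1, spacing_mm, rep(1, 4))[1:8]
  w_f32(pixdim)                     # pixdim[8]
  w_f32(352)                        # vox_offset
  w_f32(1); w_f32(0)                # scl_slope, scl_inter
  w_raw(132L)                       # slice_end .. aux_file (unused here)
  w_i16(0L)                         # qform_code
  w_i16(1L)                         # sform_code
  w_f32(rep(0, 6))                  # quatern b,c,d, qoffset x,y,z
  w_f32(c(spacing_mm[1], 0, 0, 0))  # srow_x
  w_f32(c(0, spacing_mm[2], 0, 0))  # srow_y
  w_f32(c(0, 0, spacing_mm[3], 0))  # srow_z
  w_raw(16L)                        # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)  # magic
  w_raw(4L)                         # extension flag
  vals <- as.vector(data)
  switch(as.character(dt),
    "2"  = writeBin(as.integer(vals), con, size = 1L, endian = "little"),
    "8"  = writeBin(as.integer(vals), con, size = 4L, endian = "little"),
    "16" = writeBin(as.numeric(vals), con, size = 4L, endian = "little"),
    "64" = writeBin(as.numeric(vals), con, size = 8L, endian = "little"),
    stop_mdaqp("unsupported write datatype %d", dt))
  invisible(path)
}
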