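#' Minimal NIfTI-1 volume I/O
#'
#' Self-contained single-file NIfTI-1 (`.nii` / `.nii.gz`) reader and writer
#' for the volumes this pipeline produces: isotropic 3D scalar grids.
#' No NIfTI package is available in the target R environment, and the
#' NIfTI-1 format (fixed 348-byte header + raw data) is small enough to
#' support directly. The writer stores the voxel size in `pixdim` and an
#' RAS-aligned diagonal sform whose translation places the grid center at
#' `origin`. Complex volumes are not written (store magnitude/real parts).
#'
#' @param grid a [volume_grid] with real values.
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @param datatype `"float64"`, `"float32"` or `"uint8"` (for masks).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(grid, path, datatype = c("float64", "float32", "uint8")) {
  datatype <- match.arg(datatype)
  if (is.complex(grid$values))
    stop("write_nifti: complex volumes are not supported; write Mod()/Re() parts")
  code <- switch(datatype, float64 = 64L, float32 = 16L, uint8 = 2L)
  bitpix <- switch(datatype, float64 = 64L, float32 = 32L, uint8 = 8L)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wpad <- function(len, s = "") {
    raw <- charToRaw(s)
    writeBin(c(raw, raw(len - length(raw))), con)
  }
  n <- grid$shape
  dx <- grid$voxel_size
  # physical position of the first voxel center (see volume_grid coordinates)
  first <- grid$origin - (n / 2) * dx

  wi(348, 4)                         # sizeof_hdr
  wpad(10); wpad(18)                 # data_type, db_name (legacy, unused)
  wi(0, 4); wi(0, 2); wpad(1, "r"); wpad(1)  # extents, session_error, regular, dim_info
  wi(c(3, n, 1, 1, 1, 1), 2)         # dim[8]
  wf(c(0, 0, 0))                     # intent_p1..p3
  wi(0, 2)                           # intent_code
  wi(code, 2); wi(bitpix, 2)         # datatype, bitpix
  wi(0, 2)                           # slice_start
  wf(c(1, dx, dx, dx, 0, 0, 0, 0))   # pixdim[8] (qfac = 1)
  wf(352)                            # vox_offset
  wf(1); wf(0)                       # scl_slope, scl_inter
  wi(0, 2); wpad(1); wpad(1, rawToChar(as.raw(2L)))  # slice_end, slice_code, xyzt_units = mm
  wf(c(0, 0)); wf(0); wf(0)          # cal_max, cal_min, slice_duration, toffset
  wi(c(0, 0), 4)                     # glmax, glmin (legacy)
  wpad(80, "naquant volume"); wpad(24)  # descrip, aux_file
  wi(0, 2); wi(1, 2)                 # qform_code = 0, sform_code = 1
  wf(c(0, 0, 0)); wf(c(0, 0, 0))     # quatern b/c/d, qoffset x/y/z
  wf(c(dx, 0, 0, first[1]))          # srow_x
  wf(c(0, dx, 0, first[2]))          # srow_y
  wf(c(0, 0, dx, first[3]))          # srow_z
  wpad(16)                           # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)  # magic
  writeBin(raw(4), con)              # extension flag: none (data at 352)
  v <- grid$values
  if (datatype == "uint8") {
    writeBin(as.raw(pmin(pmax(round(as.numeric(v)), 0), 255)), con)
  } else {
    writeBin(as.numeric(v), con, size = bitpix / 8, endian = "little")
  }
  invisible(path)
}

#' @rdname write_nifti
#' @return `read_nifti()` returns a [volume_grid].
#' @export
read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  ri <- function(k, size) readBin(con, "integer", n = k, size = size, endian = "little")
  rf <- function(k) readBin(con, "numeric", n = k, size = 4, endian = "little")
  if (ri(1, 4) != 348) stop("read_nifti: not a NIfTI-1 file (bad sizeof_hdr)")
  readBin(con, "raw", n = 36)        # up to dim[]
  dims <- ri(8, 2)
  if (dims[1] != 3 || length(unique(dims[2:4])) != 1)
    stop("read_nifti: only isotropic 3D volumes are supported")
  n <- dims[2:4]
  rf(3); ri(1, 2)                    # intent_p, intent_code
  code <- ri(1, 2); bitpix <- ri(1, 2); ri(1, 2)
  pixdim <- rf(8)
  vox_offset <- rf(1)
  scl_slope <- rf(1); scl_inter <- rf(1)
  readBin(con, "raw", n = 2 + 1 + 1 + 8 + 4 + 4 + 8 + 80 + 24)
  ri(1, 2)                           # qform_code
  sform_code <- ri(1, 2)
  rf(6)                              # quaternion fields
  srow <- matrix(rf(12), nrow = 3, byrow = TRUE)
  readBin(con, "raw", n = 16 + 4)    # intent_name, magic
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = skip)
  nv <- prod(n)
  v <- switch(as.character(code),
    "2"  = as.numeric(readBin(con, "integer", n = nv, size = 1, signed = FALSE)),
    "4"  = as.numeric(readBin(con, "integer", n = nv, size = 2, endian = "little")),
    "8"  = as.numeric(readBin(con, "integer", n = nv, size = 4, endian = "little")),
    "16" = readBin(con, "numeric", n = nv, size = 4, endian = "little"),
    "64" = readBin(con, "numeric", n = nv, size = 8, endian = "little"),
    stop(sprintf("read_nifti: unsupported datatype code %d", code)))
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    v <- v * scl_slope + scl_inter
  dx <- pixdim[2]
  if (sform_code > 0) {
    if (any(abs(srow[, 1:3] - diag(srow[1, 1], 3)) > 1e-4 * abs(srow[1, 1])))
      stop("read_nifti: only axis-aligned diagonal sforms are supported")
    dx <- srow[1, 1]
    first <- srow[, 4]
  } else {
    first <- -(n / 2) * dx
  }
  origin <- first + (n / 2) * dx
  volume_grid(array(v, dim = n), voxel_size = dx, origin = origin)
}
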