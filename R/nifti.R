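# Minimal NIfTI-1 I/O.
#
# Only the single-file (.nii / .nii.gz) flavour is supported, with axis-aligned
# geometry: the sform/qform rotation must be diagonal with positive entries,
# which is what this package writes and what isotropically resampled research
# volumes typically carry. Datatypes: uint8, int16, int32, float32, float64.

NIFTI_DT <- list(`2`  = list(what = "integer", size = 1L, signed = FALSE),
                 `4`  = list(what = "integer", size = 2L, signed = TRUE),
                 `8`  = list(what = "integer", size = 4L, signed = TRUE),
                 `16` = list(what = "double",  size = 4L, signed = TRUE),
                 `64` = list(what = "double",  size = 8L, signed = TRUE))

nifti_fmt_error <- function(field, detail) {
  stop(sprintf("malformed NIfTI-1 file: bad '%s' (%s)", field, detail),
       call. = FALSE)
}

#' Read a NIfTI-1 volume
#'
#' Reads a `.nii` or `.nii.gz` file into a [volume()]. Geometry must be
#' axis-aligned (diagonal sform/identity-quaternion qform); spacing is taken
#' from `pixdim`, the world origin from the sform translation (or qoffset).
#'
#' @param path path to a NIfTI-1 file.
#' @param task task label to attach (`"chest"` or `"brain"`).
#' @return a [volume()].
#' @export
read_volume <- function(path, task = c("chest", "brain")) {
  task <- match.arg(task)
  con <- gzfile(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L)
    nifti_fmt_error("sizeof_hdr", "file shorter than the 348-byte header")
  endian <- "little"
  rd <- function(off, what, n, size, signed = TRUE) {
    readBin(hdr[(off + 1L):(off + n * size)], what, n = n, size = size,
            endian = endian, signed = signed)
  }
  if (rd(0L, "integer", 1L, 4L) != 348L) {
    endian <- "big"
    if (rd(0L, "integer", 1L, 4L) != 348L)
      nifti_fmt_error("sizeof_hdr", "expected 348 in either byte order")
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1"))
    nifti_fmt_error("magic", sprintf("got '%s', expected 'n+1'", magic))
  dim0 <- rd(40L, "integer", 8L, 2L)
  ndim <- dim0[1]
  if (ndim < 1L || ndim > 7L)
    nifti_fmt_error("dim[0]", sprintf("got %d, expected 1..7", ndim))
  dims <- dim0[2:(1 + ndim)]
  if (sum(dims > 1L) > 3L || ndim > 3L && any(dims[-(1:3)] > 1L))
    nifti_fmt_error("dim", sprintf("not a 3D volume: dim=[%s]",
                                   paste(dims, collapse = ",")))
  if (ndim < 3L)
    nifti_fmt_error("dim", sprintf("not a 3D volume: dim=[%s]",
                                   paste(dims, collapse = ",")))
  dims <- dims[1:3]
  datatype <- rd(70L, "integer", 1L, 2L)
  dt <- NIFTI_DT[[as.character(datatype)]]
  if (is.null(dt))
    nifti_fmt_error("datatype", sprintf("unsupported code %d", datatype))
  pixdim <- rd(76L, "double", 8L, 4L)
  spacing <- pixdim[2:4]
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    nifti_fmt_error("pixdim", "spacing entries must be positive")
  vox_offset <- rd(108L, "double", 1L, 4L)
  scl_slope <- rd(112L, "double", 1L, 4L)
  scl_inter <- rd(116L, "double", 1L, 4L)
  qform_code <- rd(252L, "integer", 1L, 2L)
  sform_code <- rd(254L, "integer", 1L, 2L)
  origin <- c(0, 0, 0)
  if (sform_code > 0L) {
    srow <- rbind(rd(280L, "double", 4L, 4L),
                  rd(296L, "double", 4L, 4L),
                  rd(312L, "double", 4L, 4L))
    rot <- srow[, 1:3]
    if (any(abs(rot - diag(diag(rot))) > 1e-4 * max(abs(diag(rot)), 1)) ||
        any(diag(rot) <= 0))
      nifti_fmt_error("srow_x/y/z", "only diagonal positive sform supported")
    spacing <- diag(rot)
    origin <- srow[, 4]
  } else if (qform_code > 0L) {
    quat <- rd(256L, "double", 3L, 4L)
    if (any(abs(quat) > 1e-6))
      nifti_fmt_error("quatern_b/c/d", "only identity-quaternion qform supported")
    origin <- rd(268L, "double", 3L, 4L)
  }
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip < 0L) nifti_fmt_error("vox_offset", "points inside the header")
  if (skip > 0L) readBin(con, "raw", n = skip)
  n <- prod(dims)
  vox <- readBin(con, dt$what, n = n, size = dt$size, endian = endian,
                 signed = dt$signed)
  if (length(vox) < n)
    nifti_fmt_error("data", sprintf("expected %d voxels, file holds %d",
                                    n, length(vox)))
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    vox <- vox * scl_slope + scl_inter
  volume(array(as.numeric(vox), dim = dims), spacing = spacing,
         origin = origin, task = task)
}

#' Write a volume as NIfTI-1
#'
#' Writes float32 data with a diagonal sform carrying the spacing and world
#' origin; `.gz` paths are gzip-compressed. Round-trips through
#' [read_volume()] preserve voxels to float32 precision and geometry exactly
#' (float32 header fields).
#'
#' @param vol a [volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume"))
  dims <- dim(vol$voxels)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wb <- function(x, size) writeBin(x, con, size = size, endian = "little")
  wb(348L, 4L)                                       # sizeof_hdr
  wb(raw(36L), 1L)                                   # unused through dim
  wb(as.integer(c(3L, dims, 1L, 1L, 1L, 1L)), 2L)    # dim[8]
  wb(integer(7L), 2L)                                # intent params + codes
  wb(16L, 2L)                                        # datatype = float32
  wb(32L, 2L)                                        # bitpix
  wb(0L, 2L)                                         # slice_start
  wb(c(1, vol$spacing, 0, 0, 0, 0), 4L)              # pixdim[8]
  wb(352, 4L)                                        # vox_offset
  wb(c(1, 0), 4L)                                    # scl_slope, scl_inter
  wb(0L, 2L); wb(0L, 2L)                             # slice_end, codes
  wb(c(0, 0), 4L)                                    # cal_max, cal_min
  wb(c(0, 0), 4L)                                    # slice_duration, toffset
  wb(integer(2L), 4L)                                # glmax, glmin
  desc <- charToRaw(sprintf("annoret %s volume", vol$task))
  wb(c(desc, raw(80L - length(desc))), 1L)           # descrip[80]
  wb(raw(24L), 1L)                                   # aux_file[24]
  wb(0L, 2L)                                         # qform_code
  wb(1L, 2L)                                         # sform_code
  wb(numeric(6L), 4L)                                # quatern + qoffset
  wb(c(vol$spacing[1], 0, 0, vol$origin[1]), 4L)     # srow_x
  wb(c(0, vol$spacing[2], 0, vol$origin[2]), 4L)     # srow_y
  wb(c(0, 0, vol$spacing[3], vol$origin[3]), 4L)     # srow_z
  wb(raw(16L), 1L)                                   # intent_name[16]
  wb(c(charToRaw("n+1"), raw(1L)), 1L)               # magic
  wb(raw(4L), 1L)                                    # extension flag
  wb(as.numeric(vol$voxels), 4L)
  invisible(path)
}
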