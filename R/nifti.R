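# Minimal native NIfTI-1 I/O.
#
# No NIfTI package ships with the target environment, and the format's
# single-file variant is a fixed 348-byte header followed by the voxel
# stream, so reading and writing are done directly with readBin/writeBin
# over a gzip connection (.nii.gz).  Only the fields this pipeline needs
# are honoured: dim, datatype, pixdim (incl. the repetition time in
# pixdim[4]), scl_slope/scl_inter, xyzt_units, the sform affine and the
# magic.  The writer always emits little-endian; the reader honours the
# byte order declared by sizeof_hdr.

NIFTI_DT <- list(
  uint8   = list(code = 2L,  size = 1L, what = "integer", signed = FALSE),
  int16   = list(code = 4L,  size = 2L, what = "integer", signed = TRUE),
  int32   = list(code = 8L,  size = 4L, what = "integer", signed = TRUE),
  float32 = list(code = 16L, size = 4L, what = "double",  signed = TRUE),
  float64 = list(code = 64L, size = 8L, what = "double",  signed = TRUE)
)

#' Write a volumetric image as gzip-compressed NIfTI-1
#'
#' @param image a `VolumetricImage` (see [decode_2dseq()]) or a plain
#'   numeric array (affine defaults to identity).
#' @param path output path, conventionally ending in `.nii.gz`.
#' @param datatype one of `"float32"` (default; scaling baked into the
#'   data), `"int16"`, `"int32"` (raw integers preserved, slope/offset
#'   stored in the scl header fields), `"float64"`, `"uint8"`.
#' @param descrip free-text header description (<= 79 bytes).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(image, path, datatype = "float32",
                        descrip = "bru2bids") {
  if (is.array(image) || is.numeric(image)) {
    image <- volumetric_image(as.array(image), diag(4))
  }
  stopifnot(inherits(image, "VolumetricImage"))
  dt <- NIFTI_DT[[datatype]]
  if (is.null(dt)) stop("unsupported NIfTI datatype: ", datatype, call. = FALSE)

  vox <- image$voxels
  nd <- length(dim(vox))
  stopifnot(nd %in% c(2L, 3L, 4L))
  dims <- rep(1L, 8L)
  dims[1] <- nd
  dims[seq_len(nd) + 1L] <- dim(vox)

  aff <- image$affine
  voxsize <- sqrt(colSums(aff[1:3, 1:3]^2))
  pixdim <- rep(0, 8)
  pixdim[1] <- 1                       # qfac (qform unused but must be +-1)
  pixdim[2:4] <- voxsize
  if (nd == 4L) pixdim[5] <- image$repetition_time %||% 0

  scl_slope <- 1; scl_inter <- 0
  if (dt$what == "integer") {
    scl_slope <- image$value_slope %||% 1
    scl_inter <- image$value_offset %||% 0
  }

  con <- gzfile(path, "wb")
  on.exit(close(con))
  wr_i <- function(x, size) writeBin(as.integer(x), con, size = size,
                                     endian = "little")
  wr_f <- function(x) writeBin(as.double(x), con, size = 4L,
                               endian = "little")
  wr_c <- function(s, len) {
    b <- charToRaw(substr(s, 1L, len - 1L))
    writeBin(c(b, raw(len - length(b))), con)
  }
  wr_i(348L, 4L)                       # sizeof_hdr
  writeBin(raw(35L), con)              # data_type, db_name, extents, session_error, regular
  writeBin(as.raw(0L), con)            # dim_info
  wr_i(dims, 2L)                       # dim[8]
  wr_f(c(0, 0, 0))                     # intent_p1..p3
  wr_i(0L, 2L)                         # intent_code
  wr_i(dt$code, 2L)                    # datatype
  wr_i(dt$size * 8L, 2L)               # bitpix
  wr_i(0L, 2L)                         # slice_start
  wr_f(pixdim)                         # pixdim[8]
  wr_f(352)                            # vox_offset
  wr_f(scl_slope)
  wr_f(scl_inter)
  wr_i(0L, 2L)                         # slice_end
  writeBin(as.raw(0L), con)            # slice_code
  writeBin(as.raw(10L), con)           # xyzt_units: mm (2) | sec (8)
  wr_f(c(0, 0, 0, 0))                  # cal_max, cal_min, slice_duration, toffset
  wr_i(c(0L, 0L), 4L)                  # glmax, glmin
  wr_c(descrip, 80L)
  wr_c("", 24L)                        # aux_file
  wr_i(0L, 2L)                         # qform_code
  wr_i(1L, 2L)                         # sform_code: scanner coordinates
  wr_f(c(0, 0, 0))                     # quatern_b, c, d
  wr_f(c(0, 0, 0))                     # qoffset_x, y, z
  wr_f(aff[1, ])                       # srow_x
  wr_f(aff[2, ])                       # srow_y
  wr_f(aff[3, ])                       # srow_z
  wr_c("", 16L)                        # intent_name
  writeBin(c(charToRaw("n+1"), raw(1L)), con)  # magic
  writeBin(raw(4L), con)               # no extensions

  if (dt$what == "integer") {
    writeBin(as.integer(round(vox)), con, size = dt$size, endian = "little")
  } else {
    writeBin(as.double(vox), con, size = dt$size, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 image written by this package
#'
#' Supports single-file `.nii`/`.nii.gz`, both byte orders, and applies
#' scl_slope/scl_inter when set.
#'
#' @param path file path.
#' @return a `VolumetricImage` with `voxels`, `affine` (sform),
#'   `repetition_time` (seconds, 4D only) and the header `datatype` name.
#' @export
read_nifti <- function(path) {
  con <- gzfile(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 348L)
  if (length(hdr_raw) < 348L) stop("truncated NIfTI header: ", path, call. = FALSE)
  endian <- "little"
  sz <- readBin(hdr_raw[1:4], "integer", size = 4L, endian = endian)
  if (sz != 348L) {
    endian <- "big"
    sz <- readBin(hdr_raw[1:4], "integer", size = 4L, endian = endian)
    if (sz != 348L) stop("not a NIfTI-1 file: ", path, call. = FALSE)
  }
  rd_i <- function(off, n, size) readBin(hdr_raw[(off + 1L):(off + n * size)],
                                         "integer", n = n, size = size,
                                         endian = endian)
  rd_f <- function(off, n) readBin(hdr_raw[(off + 1L):(off + n * 4L)],
                                   "double", n = n, size = 4L, endian = endian)
  dims <- rd_i(40L, 8L, 2L)
  datatype_code <- rd_i(70L, 1L, 2L)
  pixdim <- rd_f(76L, 8L)
  vox_offset <- rd_f(108L, 1L)
  scl_slope <- rd_f(112L, 1L)
  scl_inter <- rd_f(116L, 1L)
  srow <- rbind(rd_f(280L, 4L), rd_f(296L, 4L), rd_f(312L, 4L))
  affine <- rbind(srow, c(0, 0, 0, 1))

  dt_name <- names(NIFTI_DT)[vapply(NIFTI_DT, function(d) d$code, 1L) ==
                             datatype_code]
  if (length(dt_name) != 1L) {
    stop("unsupported NIfTI datatype code: ", datatype_code, call. = FALSE)
  }
  dt <- NIFTI_DT[[dt_name]]
  nd <- dims[1]
  shape <- dims[seq_len(nd) + 1L]
  ntot <- prod(shape)

  skip <- vox_offset - 348L
  if (skip > 0L) readBin(con, "raw", n = skip)
  vals <- readBin(con, dt$what, n = ntot, size = dt$size,
                  signed = dt$signed, endian = endian)
  if (length(vals) != ntot) stop("truncated NIfTI data: ", path, call. = FALSE)
  if (dt$what == "integer" && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  structure(list(
    voxels = array(vals, dim = shape),
    affine = affine,
    repetition_time = if (nd == 4L) pixdim[5] else NA_real_,
    value_slope = scl_slope,
    value_offset = scl_inter,
    datatype = dt_name
  ), class = "VolumetricImage")
}
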