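# 2dseq decoding.
#
# ParaVision stores the volumetric reconstruction as a flat stream of
# frames of raw integers (or floats), x varying fastest, described by the
# sibling visu_pars file: word type, byte order, in-plane/volume matrix,
# frame count, and per-frame linear scaling (slope/offset) mapping raw
# integers to physical values.

PV_WORD_TYPES <- list(
  "_16BIT_SGN_INT"   = list(what = "integer", size = 2L, signed = TRUE),
  "_32BIT_SGN_INT"   = list(what = "integer", size = 4L, signed = TRUE),
  "_8BIT_UNSGN_INT"  = list(what = "integer", size = 1L, signed = FALSE),
  "_32BIT_FLOAT"     = list(what = "double",  size = 4L, signed = TRUE)
)

pv_endian <- function(visu) {
  bo <- pv_param(visu, "VisuCoreByteOrder", default = "littleEndian")
  if (identical(bo, "bigEndian")) "big" else "little"
}

#' Construct a volumetric image
#'
#' @param voxels 3D or 4D numeric array (x, y, z\[, t\]).
#' @param affine 4x4 voxel-to-world transform in millimetres.
#' @param repetition_time seconds (4D images).
#' @param value_slope,value_offset linear scaling already applied to (or,
#'   for integer-preserving output, still to be applied to) the voxels.
#' @return object of class `VolumetricImage`.
#' @export
volumetric_image <- function(voxels, affine, repetition_time = NA_real_,
                             value_slope = 1, value_offset = 0) {
  stopifnot(length(dim(voxels)) %in% c(2L, 3L, 4L),
            identical(dim(affine), c(4L, 4L)))
  if (abs(det(affine[1:3, 1:3])) < .Machine$double.eps) {
    stop("affine rotation block is singular", call. = FALSE)
  }
  structure(list(voxels = voxels, affine = affine,
                 repetition_time = repetition_time,
                 value_slope = value_slope, value_offset = value_offset),
            class = "VolumetricImage")
}

#' @export
print.VolumetricImage <- function(x, ...) {
  cat(sprintf("<VolumetricImage %s, TR %s s>\n",
              paste(dim(x$voxels), collapse = "x"),
              ifelse(is.na(x$repetition_time), "-",
                     format(x$repetition_time))))
  invisible(x)
}

# Resolve the frame layout declared by visu_pars:
# 3-element VisuCoreSize -> each frame is one volume (frames = timepoints);
# 2-element VisuCoreSize -> frames are slices x timepoints with the slice
# count in VisuCoreSlicePacksSlices, slices varying fastest.
visu_geometry <- function(visu) {
  size <- pv_param(visu, "VisuCoreSize")
  if (is.null(size)) stop("visu_pars lacks VisuCoreSize", call. = FALSE)
  frames <- as.integer(pv_param(visu, "VisuCoreFrameCount", default = 1))
  if (length(size) == 3L) {
    list(nx = size[1], ny = size[2], nz = size[3], nt = frames,
         frame_len = prod(size))
  } else if (length(size) == 2L) {
    nz <- as.integer(pv_param(visu, "VisuCoreSlicePacksSlices", default = 1))
    if (frames %% nz != 0L) {
      stop(sprintf("frame count %d does not factor as %d slices x timepoints",
                   frames, nz), call. = FALSE)
    }
    list(nx = size[1], ny = size[2], nz = nz, nt = frames %/% nz,
         frame_len = prod(size))
  } else {
    stop("unsupported VisuCoreSize dimensionality: ", length(size),
         call. = FALSE)
  }
}

#' Decode a 2dseq byte stream into a volumetric image
#'
#' @param data raw vector (content of a `2dseq` file) or a path to one.
#' @param visu the sibling `visu_pars` `ParameterDict`.
#' @param apply_scaling apply the per-frame slope/offset (default); when
#'   `FALSE` the raw integers are kept and the (then necessarily uniform)
#'   slope/offset are recorded on the image for deferred scaling.
#' @return a `VolumetricImage`; 4D when the frame layout yields more than
#'   one timepoint, 3D otherwise.  `repetition_time` is sourced from
#'   `VisuAcqRepetitionTime` (milliseconds in ParaVision, converted to
#'   seconds).
#' @export
decode_2dseq <- function(data, visu, apply_scaling = TRUE) {
  if (is.character(data)) {
    data <- readBin(data, "raw", n = file.size(data))
  }
  wt_name <- pv_param(visu, "VisuCoreWordType", default = NA_character_)
  wt <- PV_WORD_TYPES[[wt_name]]
  if (is.null(wt)) {
    stop(sprintf("unsupported 2dseq word type: %s",
                 ifelse(is.na(wt_name), "<missing>", wt_name)), call. = FALSE)
  }
  geo <- visu_geometry(visu)
  # frames are planes for 2D layouts, whole volumes for 3D layouts
  nframes <- if (geo$frame_len == geo$nx * geo$ny * geo$nz) geo$nt
             else geo$nz * geo$nt
  ntot <- geo$nx * geo$ny * geo$nz * geo$nt
  expected <- ntot * wt$size
  if (length(data) != expected) {
    stop(sprintf("corrupt 2dseq: expected %d bytes (%s, %dx%dx%dx%d), got %d",
                 expected, wt_name, geo$nx, geo$ny, geo$nz, geo$nt,
                 length(data)), call. = FALSE)
  }
  vals <- readBin(data, wt$what, n = ntot, size = wt$size,
                  signed = wt$signed, endian = pv_endian(visu))

  slope <- as.numeric(pv_param(visu, "VisuCoreDataSlope", default = 1))
  offs  <- as.numeric(pv_param(visu, "VisuCoreDataOffs",  default = 0))
  if (!length(slope) %in% c(1L, nframes) || !length(offs) %in% c(1L, nframes)) {
    stop(sprintf("slope/offset arrays (lengths %d/%d) do not match %d frames",
                 length(slope), length(offs), nframes), call. = FALSE)
  }
  if (apply_scaling) {
    if (length(slope) > 1L || length(offs) > 1L) {
      per_frame_s <- rep(slope, length.out = nframes)
      per_frame_o <- rep(offs,  length.out = nframes)
      vals <- vals * rep(per_frame_s, each = geo$frame_len) +
              rep(per_frame_o, each = geo$frame_len)
    } else if (slope != 1 || offs != 0) {
      vals <- vals * slope + offs
    }
    out_slope <- 1; out_offs <- 0
  } else {
    if (length(unique(slope)) > 1L || length(unique(offs)) > 1L) {
      stop("deferred scaling requires uniform slope/offset across frames",
           call. = FALSE)
    }
    out_slope <- slope[1]; out_offs <- offs[1]
  }

  shape <- c(geo$nx, geo$ny, geo$nz, geo$nt)
  if (geo$nt == 1L) shape <- shape[1:3]
  vals <- as.double(vals)
  tr_ms <- pv_param(visu, "VisuAcqRepetitionTime", default = NA_real_)[1]
  volumetric_image(array(vals, dim = shape), build_affine(visu),
                   repetition_time = as.numeric(tr_ms) / 1000,
                   value_slope = out_slope, value_offset = out_offs)
}

#' Encode a numeric array as a 2dseq byte stream
#'
#' Inverse of [decode_2dseq()]; used by the fixture generator and as the
#' round-trip oracle.  For integer word types the values are divided by
#' `slope`, shifted by `-offset` and rounded.
#'
#' @param voxels numeric array.
#' @param word_type one of the ParaVision word-type names (e.g.
#'   `"_16BIT_SGN_INT"`).
#' @param byte_order `"littleEndian"` or `"bigEndian"`.
#' @param slope,offset linear scaling (scalar or per-frame vector; frames
#'   are x*y planes for 2D layouts, volumes for 3D layouts — the caller
#'   passes `frame_len` accordingly).
#' @param frame_len number of voxels per frame when slope/offset are
#'   per-frame vectors.
#' @return raw vector.
#' @export
encode_2dseq <- function(voxels, word_type = "_16BIT_SGN_INT",
                         byte_order = "littleEndian", slope = 1, offset = 0,
                         frame_len = length(voxels)) {
  wt <- PV_WORD_TYPES[[word_type]]
  if (is.null(wt)) stop("unsupported word type: ", word_type, call. = FALSE)
  vals <- as.vector(voxels)
  nframes <- length(vals) %/% frame_len
  s <- rep(rep(slope,  length.out = max(nframes, 1L)), each = frame_len)[seq_along(vals)]
  o <- rep(rep(offset, length.out = max(nframes, 1L)), each = frame_len)[seq_along(vals)]
  raw_vals <- (vals - o) / s
  endian <- if (identical(byte_order, "bigEndian")) "big" else "little"
  if (wt$what == "integer") {
    writeBin(as.integer(round(raw_vals)), raw(), size = wt$size,
             endian = endian)
  } else {
    writeBin(as.double(raw_vals), raw(), size = wt$size, endian = endian)
  }
}

#' Build the voxel-to-world affine from visu_pars geometry
#'
#' Voxel sizes are `VisuCoreExtent / VisuCoreSize` (for 2D layouts the
#' through-plane size is `VisuCoreFrameThickness`); the direction cosines
#' come from the row-major 3x3 `VisuCoreOrientation` matrix and the
#' translation from the first triple of `VisuCorePosition`.  When any
#' geometry field is missing, a diagonal affine from the voxel sizes is
#' returned with a warning.
#'
#' @param visu `ParameterDict` from `visu_pars`.
#' @return 4x4 numeric matrix (millimetres).
#' @export
build_affine <- function(visu) {
  geo <- visu_geometry(visu)
  size <- pv_param(visu, "VisuCoreSize")
  extent <- pv_param(visu, "VisuCoreExtent")
  if (is.null(extent) || length(extent) != length(size)) {
    warning("visu_pars lacks VisuCoreExtent; assuming unit voxels",
            call. = FALSE)
    extent <- size
  }
  voxsize <- extent / size
  if (length(size) == 2L) {
    thick <- pv_param(visu, "VisuCoreFrameThickness", default = 1)
    voxsize <- c(voxsize, thick[1])
  }
  orient <- pv_param(visu, "VisuCoreOrientation", default = NULL)
  pos <- pv_param(visu, "VisuCorePosition", default = NULL)
  if (is.null(orient) || length(orient) < 9L || is.null(pos) ||
      length(pos) < 3L) {
    warning("visu_pars lacks orientation/position; using diagonal affine",
            call. = FALSE)
    aff <- diag(c(voxsize, 1))
    return(aff)
  }
  # row-major direction-cosine matrix; its transpose maps image axes to
  # world axes
  rot <- t(matrix(orient[1:9], nrow = 3L, byrow = TRUE))
  aff <- diag(4)
  aff[1:3, 1:3] <- rot %*% diag(voxsize)
  aff[1:3, 4] <- pos[1:3]
  aff
}

#' Reorient an image to the closest RAS orientation
#'
#' Permutes and flips the voxel axes so that the affine's rotation block
#' is as close to a positive diagonal as possible; world coordinates of
#' every voxel are preserved.
#'
#' @param image a `VolumetricImage`.
#' @return the reoriented `VolumetricImage`.
#' @export
reorient_canonical <- function(image) {
  aff <- image$affine
  rot <- aff[1:3, 1:3]
  perm <- integer(3)
  flip <- logical(3)
  taken <- logical(3)
  for (i in 1:3) {
    cand <- abs(rot[, i])
    cand[taken] <- -Inf
    j <- which.max(cand)
    perm[i] <- j           # voxel axis i is dominantly world axis j
    flip[i] <- rot[j, i] < 0
    taken[j] <- TRUE
  }
  vox <- image$voxels
  nd <- length(dim(vox))
  dims <- dim(vox)

  # flip axes with negative dominant direction
  idx <- lapply(seq_len(nd), function(k) seq_len(dims[k]))
  for (i in 1:3) if (flip[i]) idx[[i]] <- rev(idx[[i]])
  vox <- do.call(`[`, c(list(vox), idx, list(drop = FALSE)))
  for (i in 1:3) {
    if (flip[i]) {
      aff[, 4] <- aff[, 4] + aff[, i] * (dims[i] - 1)
      aff[, i] <- -aff[, i]
    }
  }
  # permute so voxel axis order matches world axis order
  ord <- order(perm)
  if (!identical(ord, 1:3)) {
    full_ord <- c(ord, seq_len(nd)[-(1:3)])
    vox <- aperm(vox, full_ord)
    aff[, 1:3] <- aff[, ord]
  }
  out <- image
  out$voxels <- vox
  out$affine <- aff
  out
}
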