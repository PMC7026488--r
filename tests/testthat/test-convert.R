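# visu_pars dictionaries built in code for decoder tests
make_visu <- function(size, frames = 1L, word = "_16BIT_SGN_INT",
                      order = "littleEndian", slope = 1, offset = 0,
                      nslices = NULL, extent = NULL, orient = NULL,
                      pos = NULL, tr_ms = 1000) {
  entries <- list(VisuCoreSize = size, VisuCoreFrameCount = frames,
                  VisuCoreWordType = word, VisuCoreByteOrder = order,
                  VisuCoreDataSlope = slope, VisuCoreDataOffs = offset,
                  VisuAcqRepetitionTime = tr_ms)
  if (!is.null(nslices)) entries$VisuCoreSlicePacksSlices <- nslices
  if (!is.null(extent)) entries$VisuCoreExtent <- extent
  if (!is.null(orient)) entries$VisuCoreOrientation <- orient
  if (!is.null(pos)) entries$VisuCorePosition <- pos
  if (length(size) == 2L) entries$VisuCoreFrameThickness <- 1
  parse_parameter_file(bru2bids:::format_parameter_file(entries))
}

test_that("2x2 int16 decode with identity and linear scaling", {
  raw <- writeBin(0:3, raw(), size = 2L, endian = "little")
  visu <- make_visu(c(2L, 2L), frames = 1L, nslices = 1L)
  suppressWarnings(img <- decode_2dseq(raw, visu))
  expect_identical(as.vector(img$voxels), c(0, 1, 2, 3))
  expect_identical(dim(img$voxels), c(2L, 2L, 1L))

  visu2 <- make_visu(c(2L, 2L), frames = 1L, nslices = 1L, slope = 2.5)
  suppressWarnings(img2 <- decode_2dseq(raw, visu2))
  expect_identical(as.vector(img2$voxels), c(0, 2.5, 5.0, 7.5))
})

test_that("encode -> decode round-trips exactly for integer word types", {
  set.seed(7)
  for (word in c("_16BIT_SGN_INT", "_32BIT_SGN_INT", "_8BIT_UNSGN_INT")) {
    for (order in c("littleEndian", "bigEndian")) {
      lim <- if (word == "_8BIT_UNSGN_INT") c(0L, 255L) else c(-999L, 999L)
      arr <- array(sample(lim[1]:lim[2], 8 * 8 * 4 * 10, replace = TRUE),
                   dim = c(8, 8, 4, 10))
      bytes <- encode_2dseq(arr, word_type = word, byte_order = order)
      visu <- make_visu(c(8L, 8L, 4L), frames = 10L, word = word,
                        order = order)
      suppressWarnings(img <- decode_2dseq(bytes, visu))
      expect_identical(as.vector(img$voxels), as.vector(arr) * 1.0,
                       info = paste(word, order))
      # encode(decode()) byte-stability
      expect_identical(encode_2dseq(img$voxels, word_type = word,
                                    byte_order = order), bytes)
    }
  }
})

test_that("scaling linearity: decode(R, s, o) == s * decode(R, 1, 0) + o", {
  set.seed(11)
  arr <- array(sample(-500:500, 8 * 8 * 4 * 6, replace = TRUE),
               dim = c(8, 8, 4, 6))
  bytes <- encode_2dseq(arr)
  slopes <- round(stats::runif(6, 0.5, 3), 3)   # per-frame (volume) slopes
  offs <- round(stats::rnorm(6), 3)
  visu_id <- make_visu(c(8L, 8L, 4L), frames = 6L)
  visu_sc <- make_visu(c(8L, 8L, 4L), frames = 6L, slope = slopes,
                       offset = offs)
  suppressWarnings(plain <- decode_2dseq(bytes, visu_id)$voxels)
  suppressWarnings(scaled <- decode_2dseq(bytes, visu_sc)$voxels)
  expected <- sweep(sweep(plain, 4, slopes, `*`), 4, offs, `+`)
  expect_equal(scaled, expected, tolerance = 1e-7)
})

test_that("byte-count mismatch and unknown word types are informative errors", {
  visu <- make_visu(c(4L, 4L, 2L), frames = 1L)
  expect_error(decode_2dseq(raw(10), visu), "expected 64 bytes.*got 10")
  visu_bad <- make_visu(c(4L, 4L, 2L), word = "_64BIT_SGN_INT")
  expect_error(decode_2dseq(raw(64), visu_bad), "unsupported 2dseq word type")
  # frame count that does not factor as slices x timepoints
  visu_nf <- make_visu(c(4L, 4L), frames = 7L, nslices = 3L)
  expect_error(decode_2dseq(raw(1), visu_nf), "does not factor")
})

test_that("affine: voxel sizes from extent/size, orientation and position", {
  visu <- make_visu(c(16L, 16L, 8L), extent = c(16, 16, 8),
                    orient = c(1, 0, 0, 0, 1, 0, 0, 0, 1),
                    pos = c(0, 0, 0))
  expect_equal(build_affine(visu), diag(4))

  visu2 <- make_visu(c(16L, 16L, 8L), extent = c(32, 32, 8),
                     orient = c(1, 0, 0, 0, 1, 0, 0, 0, 1),
                     pos = c(0, 0, 0))
  expect_equal(diag(build_affine(visu2))[1:3], c(2, 2, 1))

  # missing geometry falls back to a diagonal affine with a warning
  visu3 <- make_visu(c(4L, 4L, 2L), extent = c(8, 8, 2))
  expect_warning(aff <- build_affine(visu3), "diagonal affine")
  expect_equal(diag(aff)[1:3], c(2, 2, 1))
})

test_that("fixture corner world coordinates match the generator ground truth", {
  dir <- withr::local_tempdir()
  st <- make_study(dir, seed = 3L)
  loaded <- load_study(st$path)
  for (scan in loaded$scans) {
    truth <- st$scans[[as.character(scan$scan_number)]]
    aff <- build_affine(scan$visu)
    dims <- dim(truth$voxels)[1:3]
    corners_vox <- rbind(c(0, 0, 0), c(dims[1] - 1, 0, 0),
                         c(0, dims[2] - 1, 0), c(0, 0, dims[3] - 1))
    world <- t(apply(corners_vox, 1, function(ijk) {
      (aff %*% c(ijk, 1))[1:3]
    }))
    expect_equal(world, truth$corner_coords, tolerance = 1e-12)
  }
})

test_that("decoded fixture scans equal generator voxels; 90-degree orientation maps corners", {
  dir <- withr::local_tempdir()
  st <- make_study(dir, seed = 5L)
  loaded <- load_study(st$path)
  for (scan in loaded$scans) {
    truth <- st$scans[[as.character(scan$scan_number)]]
    img <- decode_2dseq(scan$data_path, scan$visu)
    expect_equal(img$voxels, truth$voxels, tolerance = 1e-7)
    expect_identical(img$repetition_time, truth$repetition_time)
  }

  # explicit 90-degree rotation about z: voxel x axis -> world y
  rot90 <- c(0, 1, 0, -1, 0, 0, 0, 0, 1)  # row-major direction cosines
  visu <- make_visu(c(4L, 4L, 2L), extent = c(8, 8, 2), orient = rot90,
                    pos = c(1, 2, 3))
  aff <- build_affine(visu)
  # independent expectation: transpose of the row-major matrix, scaled
  rt <- t(matrix(rot90, 3, byrow = TRUE)) %*% diag(c(2, 2, 1))
  expect_equal(aff[1:3, 1:3], rt)
  expect_equal((aff %*% c(3, 0, 0, 1))[1:3],
               as.vector(rt %*% c(3, 0, 0) + c(1, 2, 3)))
})

test_that("NIfTI write/read round-trip and nibabel cross-check", {
  dir <- withr::local_tempdir()
  arr <- array(stats::rnorm(6 * 5 * 4 * 3), dim = c(6, 5, 4, 3))
  img <- volumetric_image(arr, diag(c(0.5, 0.5, 1.5, 1)),
                          repetition_time = 1.5)
  path <- file.path(dir, "x.nii.gz")
  write_nifti(img, path)
  rb <- read_nifti(path)
  expect_equal(rb$voxels, arr, tolerance = 1e-6)   # float32 rounding
  expect_identical(dim(rb$voxels), dim(arr))
  expect_equal(rb$repetition_time, 1.5)
  expect_equal(rb$affine, diag(c(0.5, 0.5, 1.5, 1)), tolerance = 1e-6)

  # 3D image: header dim count 3
  img3 <- volumetric_image(arr[, , , 1], diag(4))
  path3 <- file.path(dir, "y.nii.gz")
  write_nifti(img3, path3)
  expect_identical(length(dim(read_nifti(path3)$voxels)), 3L)

  # independent oracle: nibabel reads the same shape, TR and data
  script <- paste(
    "import nibabel, numpy, sys",
    sprintf("im = nibabel.load(%s)", shQuote(path)),
    "print(im.shape)",
    "print(float(im.header['pixdim'][4]))",
    "print(float(numpy.asarray(im.dataobj).sum()))",
    sep = "; ")
  out <- system2("python", c("-c", shQuote(script)), stdout = TRUE)
  expect_identical(out[1], "(6, 5, 4, 3)")
  expect_equal(as.numeric(out[2]), 1.5, tolerance = 1e-6)
  expect_equal(as.numeric(out[3]), sum(rb$voxels), tolerance = 1e-3)
})

test_that("integer-preserving write keeps raw values with scl fields", {
  dir <- withr::local_tempdir()
  arr <- array(sample(-100:100, 4 * 4 * 2, replace = TRUE), dim = c(4, 4, 2))
  img <- volumetric_image(arr, diag(4), value_slope = 2.5, value_offset = 1)
  path <- file.path(dir, "int.nii.gz")
  write_nifti(img, path, datatype = "int16")
  rb <- read_nifti(path)
  expect_equal(rb$voxels, arr * 2.5 + 1)  # reader applies scl scaling
  expect_identical(rb$datatype, "int16")
})

test_that("canonical reorientation preserves world coordinates", {
  arr <- array(seq_len(4 * 3 * 2), dim = c(4, 3, 2))
  aff <- diag(4)
  aff[1:3, 1:3] <- matrix(c(0, -2, 0, 1, 0, 0, 0, 0, 3), 3)  # permuted + flip
  aff[1:3, 4] <- c(5, 6, 7)
  img <- volumetric_image(arr, aff)
  can <- reorient_canonical(img)
  rot <- can$affine[1:3, 1:3]
  expect_true(all(diag(rot) > 0))
  expect_equal(sum(abs(rot) > 1e-9), 3L)  # diagonal
  # same world sample: voxel (i,j,k) in original must appear at the
  # index the new affine assigns to its world position
  for (ijk in list(c(0, 0, 0), c(3, 2, 1), c(1, 0, 1))) {
    world <- (img$affine %*% c(ijk, 1))[1:3]
    new_ijk <- round(solve(can$affine) %*% c(world, 1))[1:3]
    expect_equal(can$voxels[new_ijk[1] + 1, new_ijk[2] + 1, new_ijk[3] + 1],
                 img$voxels[ijk[1] + 1, ijk[2] + 1, ijk[3] + 1])
  }
})
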