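# Synthetic ParaVision study generator.
#
# A deterministic stand-in for a real multi-species scanner archive:
# writes complete PV 6.x-style study directories (subject file, scan
# program, per-scan acqp/method/visu_pars/2dseq) with fully known ground
# truth, including compliant, non-compliant and corrupted variants.  The
# generator doubles as the format-dialect authority: whatever it writes,
# the parsers must read.

# run `code` under a fixed RNG seed without disturbing the caller's RNG
with_fixture_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Specify one synthetic scan
#'
#' @param scan_number numbered ParaVision scan directory.
#' @param instruction_name operator instruction name (BIDS grammar for
#'   compliant fixtures, arbitrary free text for non-compliant ones).
#' @param sequence_name acquisition method written to `acqp` (drives
#'   modality-suffix inference: FLASH -> T1w, (Turbo)RARE -> T2w).
#' @param matrix_size 2- or 3-element in-plane/volume matrix (kept small,
#'   <= 16x16x4, so suites run in seconds).
#' @param n_slices slice count for 2-element (multi-frame 2D) layouts.
#' @param n_timepoints number of volumes (1 for structural scans).
#' @param word_type,byte_order 2dseq storage format.
#' @param slope,offset per-frame (or scalar) value scaling.
#' @param tr_ms,te_ms repetition/echo time in milliseconds, as ParaVision
#'   records them.
#' @param truncate_2dseq corruption flag: drop the last byte of the
#'   2dseq stream.
#' @return object of class `FixtureScanSpec`.
#' @export
fixture_scan_spec <- function(scan_number, instruction_name,
                              sequence_name = "Bruker:EPI",
                              matrix_size = c(8L, 8L, 4L),
                              n_slices = 4L,
                              n_timepoints = 1L,
                              word_type = "_16BIT_SGN_INT",
                              byte_order = "littleEndian",
                              slope = 1, offset = 0,
                              tr_ms = 1000, te_ms = 20,
                              truncate_2dseq = FALSE) {
  stopifnot(length(matrix_size) %in% c(2L, 3L), n_timepoints >= 1L,
            scan_number >= 1L, word_type %in% names(PV_WORD_TYPES))
  structure(as.list(environment()), class = "FixtureScanSpec")
}

#' Specify one synthetic study
#'
#' @param subject,session identifiers written to the `subject` file
#'   (underscores here make the study non-compliant on purpose).
#' @param timestamp `POSIXct` acquisition onset encoded into the
#'   directory name, or `NA` for a non-conforming name.
#' @param scans list of [fixture_scan_spec()]s.
#' @param name_suffix free-text tail of the directory name.
#' @param missing_scanprogram corruption flag: omit
#'   `ScanProgram.scanProgram` (exercises the acqp fallback).
#' @return object of class `FixtureStudySpec`.
#' @export
fixture_study_spec <- function(subject, session, scans,
                               timestamp = as.POSIXct("2017-11-06 18:43:45",
                                                      tz = "UTC"),
                               name_suffix = "1_1",
                               missing_scanprogram = FALSE) {
  stopifnot(length(scans) >= 1L,
            all(vapply(scans, inherits, TRUE, "FixtureScanSpec")))
  nums <- vapply(scans, `[[`, 1L, "scan_number")
  if (anyDuplicated(nums)) stop("duplicate scan numbers in study spec",
                                call. = FALSE)
  structure(list(subject = subject, session = session, scans = scans,
                 timestamp = timestamp, name_suffix = name_suffix,
                 missing_scanprogram = missing_scanprogram),
            class = "FixtureStudySpec")
}

fixture_directory_name <- function(spec) {
  stamp <- if (is.na(spec$timestamp)) "undated" else
    format(spec$timestamp, "%Y%m%d_%H%M%S")
  paste(c(stamp, spec$subject, spec$name_suffix), collapse = "_")
}

# voxel-to-world corner positions, computed at write time from the spec's
# own geometry arithmetic (ground truth for the affine contract)
fixture_corner_coords <- function(voxsize, orient, pos, dims) {
  rot <- t(matrix(orient, nrow = 3L, byrow = TRUE))
  corners <- rbind(c(0, 0, 0), c(dims[1] - 1, 0, 0),
                   c(0, dims[2] - 1, 0), c(0, 0, dims[3] - 1))
  t(apply(corners, 1L, function(ijk) rot %*% (voxsize * ijk) + pos))
}

#' Generate a synthetic ParaVision study on disk
#'
#' Same `(spec, seed)` always produces a byte-identical directory tree.
#'
#' @param spec a [fixture_study_spec()].
#' @param parent_dir directory under which the study directory is
#'   created.
#' @param seed integer RNG seed for the voxel data.
#' @return invisibly, the ground truth: the spec plus, per scan, the
#'   scaled voxel array (`voxels`), the affine corner coordinates
#'   (`corner_coords`), and the study directory `path`.
#' @export
generate_study <- function(spec, parent_dir, seed = 1L) {
  stopifnot(inherits(spec, "FixtureStudySpec"))
  dirname_ <- fixture_directory_name(spec)
  study_dir <- file.path(parent_dir, dirname_)
  if (dir.exists(study_dir)) unlink(study_dir, recursive = TRUE)
  dir.create(study_dir, recursive = TRUE)

  # subject file; the identifier value sits on the line below its key,
  # as the redress procedure expects
  subject_entries <- list(
    SUBJECT_version = "PV 6.0.1",
    SUBJECT_id = spec$subject,
    SUBJECT_name_string = spec$subject,
    SUBJECT_study_name = spec$session,
    SUBJECT_weight = 0.02,
    SUBJECT_position = "Head_Prone"
  )
  writeLines(format_parameter_file(subject_entries, title = "subject"),
             file.path(study_dir, "subject"))

  if (!spec$missing_scanprogram) {
    sp <- c("<ScanProgram>",
            "  <title>synthetic fixture scan program</title>")
    for (sc in spec$scans) {
      sp <- c(sp, sprintf("  <list><displayName>%s (E%d)</displayName></list>",
                          sc$instruction_name, sc$scan_number))
    }
    sp <- c(sp, "</ScanProgram>")
    writeLines(sp, file.path(study_dir, "ScanProgram.scanProgram"))
  }

  truth <- list()
  for (k in seq_along(spec$scans)) {
    sc <- spec$scans[[k]]
    scan_dir <- file.path(study_dir, sc$scan_number)
    pdata <- file.path(scan_dir, "pdata", "1")
    dir.create(pdata, recursive = TRUE)

    acqp_entries <- list(
      ACQ_scan_name = sprintf("%s (E%d)", sc$instruction_name,
                              sc$scan_number),
      ACQ_method = sc$sequence_name,
      ACQ_protocol_name = sub("^Bruker:", "", sc$sequence_name),
      ACQ_repetition_time = sc$tr_ms,
      ACQ_echo_time = sc$te_ms,
      ACQ_institution = "Synthetic Imaging Center",
      ACQ_size = c(sc$matrix_size[1] * 2L, sc$matrix_size[2])
    )
    writeLines(format_parameter_file(acqp_entries, title = "acqp"),
               file.path(scan_dir, "acqp"))
    method_entries <- list(
      Method = sc$sequence_name,
      PVM_SPackArrNSlices = if (length(sc$matrix_size) == 2L) sc$n_slices
                            else sc$matrix_size[3],
      PVM_RepetitionTime = sc$tr_ms
    )
    writeLines(format_parameter_file(method_entries, title = "method"),
               file.path(scan_dir, "method"))

    is2d <- length(sc$matrix_size) == 2L
    nz <- if (is2d) sc$n_slices else sc$matrix_size[3]
    dims <- c(sc$matrix_size[1], sc$matrix_size[2], nz, sc$n_timepoints)
    nframes <- if (is2d) nz * sc$n_timepoints else sc$n_timepoints
    frame_len <- if (is2d) prod(dims[1:2]) else prod(dims[1:3])

    voxsize <- c(1.0, 1.0, if (is2d) 1.5 else 1.0) * c(0.5, 0.5, 1)
    extent <- voxsize[seq_len(length(sc$matrix_size))] *
      sc$matrix_size
    orient <- c(1, 0, 0, 0, 1, 0, 0, 0, 1)
    pos <- c(-dims[1] / 2 * voxsize[1], -dims[2] / 2 * voxsize[2], -4)

    visu_entries <- list(
      VisuCoreDim = length(sc$matrix_size),
      VisuCoreSize = sc$matrix_size,
      VisuCoreExtent = extent,
      VisuCoreFrameCount = nframes,
      VisuCoreFrameThickness = voxsize[3],
      VisuCoreWordType = sc$word_type,
      VisuCoreByteOrder = sc$byte_order,
      VisuCoreDataSlope = rep(sc$slope, length.out = nframes),
      VisuCoreDataOffs = rep(sc$offset, length.out = nframes),
      VisuCoreOrientation = orient,
      VisuCorePosition = pos,
      VisuAcqRepetitionTime = sc$tr_ms
    )
    if (is2d) visu_entries$VisuCoreSlicePacksSlices <- nz
    writeLines(format_parameter_file(visu_entries, title = "visu_pars"),
               file.path(pdata, "visu_pars"))

    # seeded voxel content: raw integers scaled per frame
    raw_vals <- with_fixture_seed(seed + sc$scan_number, {
      if (sc$word_type == "_32BIT_FLOAT") {
        round(stats::runif(prod(dims), -100, 100), 3)
      } else if (sc$word_type == "_8BIT_UNSGN_INT") {
        sample.int(255L, prod(dims), replace = TRUE) - 1L
      } else {
        sample.int(2000L, prod(dims), replace = TRUE) - 1000L
      }
    })
    s <- rep(rep(sc$slope, length.out = nframes), each = frame_len)
    o <- rep(rep(sc$offset, length.out = nframes), each = frame_len)
    scaled <- raw_vals * s + o
    bytes <- encode_2dseq(scaled, word_type = sc$word_type,
                          byte_order = sc$byte_order,
                          slope = rep(sc$slope, length.out = nframes),
                          offset = rep(sc$offset, length.out = nframes),
                          frame_len = frame_len)
    if (isTRUE(sc$truncate_2dseq)) bytes <- bytes[-length(bytes)]
    writeBin(bytes, file.path(pdata, "2dseq"))

    dims_out <- if (sc$n_timepoints == 1L) dims[1:3] else dims
    truth[[as.character(sc$scan_number)]] <- list(
      spec = sc,
      voxels = array(scaled, dim = dims_out),
      corner_coords = fixture_corner_coords(voxsize, orient, pos, dims),
      repetition_time = sc$tr_ms / 1000
    )
  }

  invisible(structure(list(spec = spec, path = study_dir,
                           directory_name = dirname_, scans = truth),
                      class = "FixtureStudy"))
}

# species vocabularies: disjoint acquisition strings and subject pools so
# per-species selectors split a mixed collection into disjoint datasets,
# while a generic "EPI"/"TurboRARE" selection picks out only the species
# whose vocabulary contains those strings
SPECIES_VOCAB <- list(
  mouse = list(func_acq = "seEPI", anat_acq = "TurboRARE",
               func_seq = "Bruker:EPI", anat_seq = "Bruker:RARE",
               subjects = c("4001", "4007", "SN9879"), session = "ses1",
               task = "rest"),
  rat = list(func_acq = "geEPI", anat_acq = "RAREst",
             func_seq = "Bruker:EPI", anat_seq = "Bruker:RARE",
             subjects = c("21", "22", "23"), session = "r1",
             task = "rest"),
  lemur = list(func_acq = "lemGE", anat_acq = "lemMSME",
               func_seq = "Bruker:FLASH", anat_seq = "Bruker:MSME",
               subjects = c("Mc365A", "Mc285AB", "Mc401B"),
               session = "P02", task = "rest")
)

#' Per-species scan selectors matching [generate_collection()]'s vocabularies
#'
#' @return named list (`mouse`, `rat`, `lemur`), each holding `func` and
#'   `anat` [scan_selector()]s scoped to that species.
#' @export
species_selectors <- function() {
  lapply(SPECIES_VOCAB, function(v) {
    list(func = scan_selector(acquisition = v$func_acq),
         anat = scan_selector(acquisition = v$anat_acq))
  })
}

#' Generate a synthetic multi-species study collection
#'
#' Emulates a scanner/server collection directory holding studies from
#' up to three species (mouse, rat, mouse lemur) with disjoint
#' acquisition-string vocabularies and subject-id pools, so that
#' selector-scoped pipeline runs split it into disjoint BIDS datasets.
#'
#' @param collection_dir target directory (created).
#' @param n_species 0..3 species included, in the order mouse, rat,
#'   lemur.
#' @param studies_per_species studies generated per species (subjects
#'   cycle through a per-species pool of 3).
#' @param seed integer RNG seed.
#' @param noncompliant_per_species additional studies per species with
#'   free-text instruction names and an underscored subject id, which the
#'   pipeline must refuse to convert until redressed.
#' @return invisibly, a list of `FixtureStudy` ground-truth objects, with
#'   the non-compliant ones carrying attribute `"compliant" = FALSE`.
#' @export
generate_collection <- function(collection_dir, n_species = 3L,
                                studies_per_species = 1L, seed = 1L,
                                noncompliant_per_species = 0L) {
  stopifnot(n_species >= 0L, n_species <= 3L)
  dir.create(collection_dir, recursive = TRUE, showWarnings = FALSE)
  out <- list()
  species <- names(SPECIES_VOCAB)[seq_len(n_species)]
  base_time <- as.POSIXct("2017-11-06 18:43:45", tz = "UTC")
  for (si in seq_along(species)) {
    v <- SPECIES_VOCAB[[species[si]]]
    total <- studies_per_species + noncompliant_per_species
    for (sj in seq_len(total)) {
      compliant <- sj <= studies_per_species
      subject <- v$subjects[(sj - 1L) %% length(v$subjects) + 1L]
      if (!compliant) subject <- paste0(subject, "_nc")
      stamp <- base_time + (si - 1L) * 86400 + (sj - 1L) * 3600
      scans <- if (compliant) list(
        fixture_scan_spec(3L,
          sprintf("acq-%s_%s", v$anat_acq, "T2w"),
          sequence_name = v$anat_seq,
          matrix_size = c(8L, 8L, 4L), n_timepoints = 1L,
          tr_ms = 4000, te_ms = 36),
        fixture_scan_spec(5L,
          sprintf("acq-%s_task-%s_bold", v$func_acq, v$task),
          sequence_name = v$func_seq,
          matrix_size = c(8L, 8L), n_slices = 4L, n_timepoints = 5L,
          slope = 2.5, offset = 0, tr_ms = 1500, te_ms = 15),
        fixture_scan_spec(7L,
          sprintf("acq-%s_task-%s_bold", v$func_acq, v$task),
          sequence_name = v$func_seq,
          matrix_size = c(8L, 8L), n_slices = 4L, n_timepoints = 5L,
          slope = 2.5, offset = 0, tr_ms = 1500, te_ms = 15)
      ) else list(
        fixture_scan_spec(3L, "anatomy scan (final)",
                          sequence_name = v$anat_seq, tr_ms = 4000),
        fixture_scan_spec(5L, "my bold run 1",
                          sequence_name = v$func_seq,
                          matrix_size = c(8L, 8L), n_slices = 4L,
                          n_timepoints = 5L, tr_ms = 1500)
      )
      spec <- fixture_study_spec(subject = subject, session = v$session,
                                 scans = scans, timestamp = stamp,
                                 name_suffix = sprintf("%d_1", sj))
      st <- generate_study(spec, collection_dir,
                           seed = seed + 1000L * si + sj)
      attr(st, "compliant") <- compliant
      attr(st, "species") <- species[si]
      out[[st$directory_name]] <- st
    }
  }
  invisible(out)
}
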