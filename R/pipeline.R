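# End-to-end repositing pipeline: collection directory -> BIDS tree.
# Stages run sequentially per scan category in a fixed order
# (structural, functional, diffusion-weighted) for reproducibility.

#' Pipeline run configuration
#'
#' @param input collection directory holding ParaVision study
#'   directories (a single study directory is also accepted).
#' @param output BIDS dataset root to create.
#' @param functional_match,structural_match,diffusion_match
#'   [scan_selector()]s (or named lists coercible to one) choosing the
#'   scans per category; at least one must be given.
#' @param workdir debuggable work directory (metadata table, run log);
#'   defaults to `<output>/work`.
#' @param run_base first run index, 0 (default) or 1.
#' @param keep_int preserve integer voxel data plus NIfTI scl
#'   slope/intercept fields instead of baking scaling into float32.
#' @param canonical reorient output images to closest RAS.
#' @param events_hook optional `function(events_path, entities, scan)`
#'   called after each functional events stub is written, for users who
#'   can supply stimulation timings from external records.
#' @return object of class `RunConfig`.
#' @export
run_config <- function(input, output, functional_match = NULL,
                       structural_match = NULL, diffusion_match = NULL,
                       workdir = file.path(output, "work"),
                       run_base = 0L, keep_int = FALSE, canonical = FALSE,
                       events_hook = NULL) {
  coerce <- function(x) {
    if (is.null(x) || inherits(x, "ScanSelector")) x else scan_selector(x)
  }
  functional_match <- coerce(functional_match)
  structural_match <- coerce(structural_match)
  diffusion_match <- coerce(diffusion_match)
  if (is.null(functional_match) && is.null(structural_match) &&
      is.null(diffusion_match)) {
    stop("at least one scan selector (functional/structural/diffusion) is required",
         call. = FALSE)
  }
  if (!dir.exists(input)) {
    stop("input collection directory does not exist: ", input, call. = FALSE)
  }
  structure(list(input = input, output = output,
                 functional_match = functional_match,
                 structural_match = structural_match,
                 diffusion_match = diffusion_match,
                 workdir = workdir, run_base = as.integer(run_base),
                 keep_int = isTRUE(keep_int), canonical = isTRUE(canonical),
                 events_hook = events_hook),
            class = "RunConfig")
}

# studies = subdirectories holding a `subject` file; a bare study
# directory passed as the collection is treated as one study
find_studies <- function(input) {
  if (file.exists(file.path(input, "subject"))) return(input)
  dirs <- list.dirs(input, recursive = FALSE)
  dirs[file.exists(file.path(dirs, "subject"))]
}

convert_one_scan <- function(scan, row, config, bids_root) {
  entities <- list(subject = row$subject, session = row$session,
                   task = row$task, acq = row$acq, run = row$run,
                   suffix = row$suffix, category = row$category)
  rel <- compose_bids_path(entities)
  nii_path <- file.path(bids_root, rel)
  dir.create(dirname(nii_path), recursive = TRUE, showWarnings = FALSE)

  if (is.na(scan$data_path) || is.null(scan$visu)) {
    warning(sprintf("scan %d (%s): no reconstruction; skipped",
                    scan$scan_number, rel), call. = FALSE)
    return(NULL)
  }
  img <- decode_2dseq(scan$data_path, scan$visu,
                      apply_scaling = !config$keep_int)
  if (config$canonical) img <- reorient_canonical(img)
  datatype <- if (config$keep_int) {
    switch(pv_param(scan$visu, "VisuCoreWordType"),
           "_16BIT_SGN_INT" = "int16", "_32BIT_SGN_INT" = "int32",
           "_8BIT_UNSGN_INT" = "uint8", "float32")
  } else "float32"
  write_nifti(img, nii_path, datatype = datatype)

  stem <- sub("\\.nii(\\.gz)?$", "", nii_path)
  write_sidecar(scan, entities, paste0(stem, ".json"))
  if (row$category == "func") {
    ev <- paste0(sub("_[A-Za-z0-9]+$", "", stem), "_events.tsv")
    write_events_stub(ev)
    if (!is.null(config$events_hook)) config$events_hook(ev, entities, scan)
  }
  if (row$category == "dwi") {
    # gradient-table sourcing from the method file is not implemented;
    # empty placeholders mark the slots
    file.create(paste0(stem, ".bval"), paste0(stem, ".bvec"))
  }
  rel
}

#' Run the full ParaVision-to-BIDS repositing pipeline
#'
#' Enumerates the studies of a collection, extracts and validates BIDS
#' entities from operator input, selects scans per category, converts
#' each matched 2dseq reconstruction to NIfTI with a sidecar (plus
#' events stub or diffusion placeholders), then writes sessions tables
#' and dataset boilerplate and runs the internal tree validator.
#'
#' @param config a [run_config()] (or arguments forwarded to it).
#' @param ... forwarded to [run_config()] when `config` is a path.
#' @return invisibly, a list with `status` (0 = clean conversion,
#'   2 = no scan matched any selector, 1 = violations found), `table`
#'   (the full candidate `MetadataTable`), `converted` (per-category
#'   tables actually converted), `violations`, `bids_root`.
#' @export
run_pipeline <- function(config, ...) {
  if (!inherits(config, "RunConfig")) config <- run_config(config, ...)
  dir.create(config$output, recursive = TRUE, showWarnings = FALSE)
  dir.create(config$workdir, recursive = TRUE, showWarnings = FALSE)

  studies <- list()
  scans_by_key <- list()
  for (p in find_studies(config$input)) {
    st <- tryCatch(load_study(p), error = function(e) {
      warning(sprintf("skipping %s: %s", p, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (is.null(st)) next
    studies[[length(studies) + 1L]] <- st
    for (sc in st$scans) {
      scans_by_key[[paste(st$path, sc$scan_number, sep = "\r")]] <- sc
    }
  }
  table <- build_metadata_table(studies)
  write_metadata_table(table, config$workdir)

  selectors <- list(anat = config$structural_match,
                    func = config$functional_match,
                    dwi = config$diffusion_match)
  converted <- list()
  for (category in names(selectors)) {
    sel <- selectors[[category]]
    if (is.null(sel) || nrow(table) == 0L) next
    rows <- select_scans(table, sel, category)
    if (nrow(rows) == 0L) next
    rows <- assign_run_numbers(rows, base = config$run_base)
    rows$bids_path <- NA_character_
    for (i in seq_len(nrow(rows))) {
      scan <- scans_by_key[[paste(rows$study_path[i], rows$scan_number[i],
                                  sep = "\r")]]
      rel <- tryCatch(convert_one_scan(scan, rows[i, ], config,
                                       config$output),
                      error = function(e) {
                        warning(sprintf("scan %d in %s failed: %s",
                                        rows$scan_number[i],
                                        rows$study_path[i],
                                        conditionMessage(e)), call. = FALSE)
                        NULL
                      })
      if (!is.null(rel)) rows$bids_path[i] <- rel
    }
    rows <- rows[!is.na(rows$bids_path), , drop = FALSE]
    if (nrow(rows) > 0L) converted[[category]] <- rows
    write_metadata_table(rows, config$workdir,
                         name = sprintf("metadata_%s.tsv", category))
  }

  all_converted <- if (length(converted) > 0L) {
    do.call(rbind, converted)
  } else empty_metadata_table()

  if (nrow(all_converted) == 0L) {
    message("no scans matched the selection criteria; nothing converted")
    return(invisible(list(status = 2L, table = table,
                          converted = all_converted,
                          violations = character(),
                          bids_root = config$output)))
  }

  write_sessions_tsv(all_converted, config$output)
  write_dataset_boilerplate(config$output,
                            name = basename(normalizePath(config$input)),
                            subjects = unique(all_converted$subject))
  violations <- validate_tree(config$output)
  if (length(violations) == 0L) {
    message(sprintf(
      "converted %d scan(s) into %s; consider checking the result with the external BIDS validator (https://bids-standard.github.io/bids-validator/)",
      nrow(all_converted), config$output))
  }
  invisible(list(status = if (length(violations) == 0L) 0L else 1L,
                 table = table, converted = all_converted,
                 violations = violations, bids_root = config$output))
}

#' Convert a ParaVision collection to BIDS (library entry point)
#'
#' Thin wrapper over [run_config()] + [run_pipeline()], mirroring the
#' command-line surface so scripted and console invocations accept the
#' same parameter set and produce identical results.
#'
#' @inheritParams run_config
#' @param ... forwarded to [run_config()].
#' @return see [run_pipeline()].
#' @export
bru2bids <- function(input, output, ...) {
  run_pipeline(run_config(input, output, ...))
}
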