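# BIDS 1.x raw-dataset emission: path grammar, sidecar JSON, events
# stubs, sessions tables, dataset boilerplate and a lightweight internal
# naming validator (the full external validator remains the authority).

BIDS_VERSION <- "1.8.0"

#' Compose a BIDS-relative path from validated entities
#'
#' Entity order is fixed (sub, ses, task, acq, run) with the modality
#' suffix last: `sub-<S>/ses-<E>/<category>/sub-<S>_ses-<E>[_task-<T>]
#' [_acq-<A>][_run-<R>]_<suffix>.<ext>`.
#'
#' @param entities named list with at least `subject`, `session`,
#'   `suffix`, `category`; optional `task`, `acq`, `run`.
#' @param extension file extension without leading dot (default
#'   `"nii.gz"`).
#' @return relative path string.
#' @examples
#' compose_bids_path(list(subject = "Mc365A", session = "R02",
#'                        task = "rest", acq = "seEPI", run = 0,
#'                        suffix = "bold", category = "func"))
#' @export
compose_bids_path <- function(entities, extension = "nii.gz") {
  need <- c("subject", "session", "suffix", "category")
  for (k in need) {
    v <- entities[[k]]
    if (is.null(v) || is.na(v) || !nzchar(as.character(v))) {
      stop(sprintf("missing mandatory entity '%s'", k), call. = FALSE)
    }
  }
  stopifnot(entities$category %in% c("anat", "func", "dwi"))
  parts <- c(sprintf("sub-%s", entities$subject),
             sprintf("ses-%s", entities$session))
  opt <- function(key, label) {
    v <- entities[[key]]
    if (!is.null(v) && !is.na(v)) sprintf("%s-%s", label, v) else NULL
  }
  name <- paste(c(parts, opt("task", "task"), opt("acq", "acq"),
                  opt("run", "run"), entities$suffix), collapse = "_")
  file.path(parts[1], parts[2], entities$category,
            paste0(name, ".", extension))
}

# Deterministic JSON: sorted keys, no rounding, trailing newline.
write_bids_json <- function(x, path) {
  x <- x[order(names(x))]
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, pretty = 2, digits = NA,
                           null = "null")
  writeLines(json, path)
  invisible(path)
}

#' Write the sidecar JSON for a converted scan
#'
#' Numeric fields use BIDS canonical units (seconds; ParaVision stores
#' milliseconds).  Source fields with no BIDS equivalent are preserved
#' under the vendor-namespaced `BrukerParaVision` key rather than at the
#' top level, so they can never collide with reserved BIDS fields.
#'
#' @param scan a `ScanRecord`.
#' @param entities entity list for the scan (determines `TaskName`).
#' @param path output path of the `.json` file.
#' @return `path`, invisibly.
#' @export
write_sidecar <- function(scan, entities, path) {
  meta <- list(Manufacturer = "Bruker")
  tr <- scan$repetition_time
  if (!is.na(tr)) meta$RepetitionTime <- tr
  te_ms <- pv_param(scan$acqp, "ACQ_echo_time", default = NA_real_)[1]
  if (!is.na(te_ms)) meta$EchoTime <- as.numeric(te_ms) / 1000
  if (!is.na(scan$sequence_name %||% NA_character_)) {
    meta$PulseSequenceType <- scan$sequence_name
  }
  if (identical(entities$category, "func") && !is.null(entities$task) &&
      !is.na(entities$task)) {
    meta$TaskName <- entities$task
  }
  vendor <- list(ScanNumber = scan$scan_number)
  for (spec in list(c("ACQ_protocol_name", "ProtocolName"),
                    c("ACQ_institution", "Institution"),
                    c("ACQ_station",     "Station"))) {
    v <- pv_param(scan$acqp, spec[1], default = NULL)
    if (!is.null(v)) vendor[[spec[2]]] <- v
  }
  vendor$InstructionName <- scan$instruction_name
  meta$BrukerParaVision <- vendor[order(names(vendor))]
  write_bids_json(meta, path)
}

#' Write an empty events stub for a functional image
#'
#' ParaVision records no stimulation information, so each functional
#' image gets a sibling `*_events.tsv` holding only the header row; the
#' user can fill, delete or ignore it (empty events files carry no
#' meaning in BIDS).
#'
#' @param path output `.tsv` path.
#' @return `path`, invisibly.
#' @export
write_events_stub <- function(path) {
  writeLines("onset\tduration", path)
  invisible(path)
}

#' Write per-subject sessions.tsv files
#'
#' One `sub-<S>/sub-<S>_sessions.tsv` per subject with columns
#' `session_id` and `acq_time` (ISO 8601 onset from the study directory
#' name; empty when the name carries no timestamp), rows sorted by
#' acquisition time.
#'
#' @param rows converted-scan `MetadataTable` (columns `subject`,
#'   `session`, `acq_time`).
#' @param bids_root dataset root.
#' @return character vector of written paths, invisibly.
#' @export
write_sessions_tsv <- function(rows, bids_root) {
  written <- character()
  for (subj in unique(rows$subject)) {
    sess <- unique(rows[rows$subject == subj, c("session", "acq_time")])
    if (nrow(sess) == 0L) next
    sess <- sess[order(sess$acq_time, sess$session, na.last = TRUE), ,
                 drop = FALSE]
    df <- data.frame(session_id = paste0("ses-", sess$session),
                     acq_time = ifelse(is.na(sess$acq_time), "",
                                       sess$acq_time),
                     stringsAsFactors = FALSE)
    path <- file.path(bids_root, paste0("sub-", subj),
                      paste0("sub-", subj, "_sessions.tsv"))
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <- c(written, path)
  }
  invisible(written)
}

#' Write dataset_description.json and participants.tsv
#'
#' @param bids_root dataset root.
#' @param name dataset name (conventionally the source collection
#'   directory name).
#' @param subjects character vector of subject identifiers.
#' @return `bids_root`, invisibly.
#' @export
write_dataset_boilerplate <- function(bids_root, name, subjects = character()) {
  dir.create(bids_root, recursive = TRUE, showWarnings = FALSE)
  write_bids_json(list(Name = name, BIDSVersion = BIDS_VERSION),
                  file.path(bids_root, "dataset_description.json"))
  if (length(subjects) > 0L) {
    df <- data.frame(participant_id = paste0("sub-", sort(unique(subjects))),
                     stringsAsFactors = FALSE)
    utils::write.table(df, file.path(bids_root, "participants.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(bids_root)
}

# filename grammar: ordered optional entities, mandatory sub/ses, suffix
BIDS_NAME_RE <- paste0(
  "^sub-[A-Za-z0-9]+_ses-[A-Za-z0-9]+",
  "(_task-[A-Za-z0-9]+)?(_acq-[A-Za-z0-9]+)?(_ce-[A-Za-z0-9]+)?",
  "(_rec-[A-Za-z0-9]+)?(_dir-[A-Za-z0-9]+)?(_run-[0-9]+)?(_echo-[0-9]+)?",
  "_[A-Za-z0-9]+\\.")

#' Validate a BIDS tree against the internal naming rules
#'
#' A lightweight desk-scale check, not a replacement for the external
#' BIDS validator: verifies `dataset_description.json` presence, filename
#' grammar and entity order, directory/filename entity agreement, and
#' that every NIfTI has exactly one sidecar JSON with the same stem.
#'
#' @param bids_root dataset root.
#' @return character vector of violations; empty on clean trees.
#' @export
validate_tree <- function(bids_root) {
  violations <- character()
  if (!file.exists(file.path(bids_root, "dataset_description.json"))) {
    violations <- c(violations, "missing dataset_description.json")
  }
  files <- list.files(bids_root, recursive = TRUE)
  data_files <- files[grepl("\\.(nii(\\.gz)?|tsv|json|bval|bvec)$", files) &
                      grepl("^sub-", files)]
  for (f in data_files) {
    base <- basename(f)
    segs <- strsplit(f, "/", fixed = TRUE)[[1]]
    if (grepl("_sessions\\.tsv$", base)) {
      ok <- grepl("^sub-[A-Za-z0-9]+_sessions\\.tsv$", base) &&
        length(segs) == 2L && segs[1] == sub("_sessions\\.tsv$", "", base)
      if (!ok) violations <- c(violations, sprintf("malformed sessions file: %s", f))
      next
    }
    if (!grepl(BIDS_NAME_RE, base)) {
      violations <- c(violations,
                      sprintf("filename violates entity grammar/order: %s", f))
      next
    }
    sub_ent <- sub("^(sub-[A-Za-z0-9]+).*", "\\1", base)
    ses_ent <- sub("^sub-[A-Za-z0-9]+_(ses-[A-Za-z0-9]+).*", "\\1", base)
    if (length(segs) != 4L || segs[1] != sub_ent || segs[2] != ses_ent ||
        !segs[3] %in% c("anat", "func", "dwi")) {
      violations <- c(violations,
                      sprintf("file not under sub/ses/category directory: %s", f))
    }
    if (grepl("\\.nii(\\.gz)?$", base)) {
      sidecar <- file.path(bids_root, dirname(f),
                           paste0(sub("\\.nii(\\.gz)?$", "", base), ".json"))
      if (!file.exists(sidecar)) {
        violations <- c(violations, sprintf("NIfTI without sidecar: %s", f))
      }
    }
  }
  violations
}
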