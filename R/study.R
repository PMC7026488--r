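#' Parse the timestamp encoded in a ParaVision study directory name
#'
#' ParaVision names study directories `YYYYMMDD_HHMMSS_<freetext>`; the
#' leading two tokens encode the acquisition onset used for the BIDS
#' `sessions.tsv` `acq_time` column.  The timestamp is never used for
#' subject identification.
#'
#' @param directory_name basename of the study directory.
#' @return `POSIXct` (UTC) on success, `NA` (missing-timestamp marker) for
#'   non-conforming names; the study remains convertible either way.
#' @examples
#' parse_directory_timestamp("20171106_184345_21_1_1")
#' @export
parse_directory_timestamp <- function(directory_name) {
  m <- regmatches(directory_name,
                  regexec("^([0-9]{8})_([0-9]{6})(_|$)", directory_name))[[1]]
  if (length(m) == 0L) return(as.POSIXct(NA))
  ts <- as.POSIXct(paste(m[2], m[3]), format = "%Y%m%d %H%M%S", tz = "UTC")
  if (is.na(ts)) return(as.POSIXct(NA))  # e.g. month 13: not a real date
  ts
}

#' Parse a ScanProgram.scanProgram file into scan entries
#'
#' The study-level scan program lists every scan on lines holding a
#' `<displayName>` tag: the operator "Instruction Name" sits between the
#' opening tag and the `" (E"` token, and the digits inside the
#' parenthesized token give the numbered scan directory.
#'
#' @param text character scalar or vector of lines.
#' @return data.frame with columns `scan_number` (integer) and
#'   `instruction_name` (character); zero rows when no line matches (the
#'   caller then falls back to per-scan `acqp` files).
#' @examples
#' parse_scan_program("<displayName>acq-seEPI_task-rest_bold (E5)</displayName>")
#' @export
parse_scan_program <- function(text) {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  }
  m <- regmatches(text,
                  regexec("<displayName>(.*) \\(E([0-9]+)\\)", text))
  hits <- m[vapply(m, length, 1L) == 3L]
  if (length(hits) == 0L) {
    return(data.frame(scan_number = integer(), instruction_name = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    scan_number = as.integer(vapply(hits, `[[`, "", 3L)),
    instruction_name = vapply(hits, `[[`, "", 2L),
    stringsAsFactors = FALSE
  )
}

# Instruction name from a scan's acqp file (ScanProgram fallback).
# ACQ_scan_name carries the same "name (E<n>)" payload as the displayName
# line; strip the scan-number token if present.
acqp_instruction_name <- function(acqp) {
  nm <- pv_param(acqp, "ACQ_scan_name", default = NA_character_)
  if (is.na(nm)) return(NA_character_)
  sub(" \\(E[0-9]+\\)$", "", nm)
}

#' Load a ParaVision study directory
#'
#' Enumerates the numbered scan subdirectories of one study, reading the
#' `subject` parameter file, the scan program (falling back to each scan's
#' `acqp` when the scan program is missing or yields no entries), and each
#' scan's `acqp` and `pdata/1/visu_pars` files.
#'
#' @param path study directory containing a `subject` file.
#' @return An object of class `StudyDirectory`: list with `path`,
#'   `directory_name`, `timestamp`, `subject_file` (`ParameterDict`),
#'   `scan_program_entries` (data.frame), and `scans` (list of `ScanRecord`,
#'   ascending scan number).  Each `ScanRecord` holds `scan_number`,
#'   `instruction_name`, `sequence_name`, `repetition_time` (seconds),
#'   `acqp`, `visu` and `data_path` (`NA` when no reconstruction exists).
#' @export
load_study <- function(path) {
  subject_path <- file.path(path, "subject")
  if (!dir.exists(path) || !file.exists(subject_path)) {
    stop(sprintf("not a ParaVision study (no subject file): %s", path),
         call. = FALSE)
  }
  subject_file <- read_parameter_file(subject_path)
  directory_name <- basename(normalizePath(path))

  sp_path <- file.path(path, "ScanProgram.scanProgram")
  sp_entries <- if (file.exists(sp_path)) {
    tryCatch(parse_scan_program(readLines(sp_path, warn = FALSE)),
             error = function(e) NULL)
  } else NULL
  if (is.null(sp_entries) || nrow(sp_entries) == 0L) sp_entries <- NULL

  scan_dirs <- list.dirs(path, recursive = FALSE, full.names = FALSE)
  scan_nums <- suppressWarnings(as.integer(scan_dirs))
  scan_nums <- sort(scan_nums[!is.na(scan_nums)])

  scans <- list()
  for (num in scan_nums) {
    scan_dir <- file.path(path, num)
    acqp_path <- file.path(scan_dir, "acqp")
    acqp <- tryCatch(read_parameter_file(acqp_path), error = function(e) NULL)

    instruction <- NA_character_
    if (!is.null(sp_entries)) {
      hit <- sp_entries$instruction_name[sp_entries$scan_number == num]
      if (length(hit) == 1L) instruction <- hit
    }
    if (is.na(instruction)) {
      if (is.null(acqp)) {
        warning(sprintf("scan %d in %s: no scan program entry and unreadable acqp; skipped",
                        num, directory_name), call. = FALSE)
        next
      }
      instruction <- acqp_instruction_name(acqp)
    }
    if (is.null(acqp)) {
      warning(sprintf("scan %d in %s: unreadable acqp; skipped",
                      num, directory_name), call. = FALSE)
      next
    }

    visu_path <- file.path(scan_dir, "pdata", "1", "visu_pars")
    data_path <- file.path(scan_dir, "pdata", "1", "2dseq")
    visu <- if (file.exists(visu_path)) read_parameter_file(visu_path) else NULL
    if (!file.exists(data_path)) data_path <- NA_character_

    tr_ms <- pv_param(acqp, "ACQ_repetition_time", default = NA_real_)[1]
    scans[[length(scans) + 1L]] <- structure(list(
      scan_number = num,
      instruction_name = instruction,
      sequence_name = pv_param(acqp, "ACQ_method", default = NA_character_),
      repetition_time = as.numeric(tr_ms) / 1000,
      acqp = acqp,
      visu = visu,
      data_path = data_path,
      scan_path = scan_dir
    ), class = "ScanRecord")
  }

  structure(list(
    path = path,
    directory_name = directory_name,
    timestamp = parse_directory_timestamp(directory_name),
    subject_file = subject_file,
    scan_program_entries = if (is.null(sp_entries)) {
      data.frame(scan_number = vapply(scans, `[[`, 1L, "scan_number"),
                 instruction_name = vapply(scans, `[[`, "", "instruction_name"),
                 stringsAsFactors = FALSE)
    } else sp_entries,
    scans = scans
  ), class = "StudyDirectory")
}

#' @export
print.StudyDirectory <- function(x, ...) {
  cat(sprintf("<StudyDirectory %s: %d scans, timestamp %s>\n",
              x$directory_name, length(x$scans),
              ifelse(is.na(x$timestamp), "missing",
                     format(x$timestamp, "%Y-%m-%dT%H:%M:%S"))))
  invisible(x)
}
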