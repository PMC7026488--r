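# BIDS raw-MRI entity short identifiers accepted in instruction names,
# in canonical filename order. sub/ses are sourced from the subject file,
# never from the instruction name, but are tolerated there.
BIDS_SHORT_IDS <- c("sub", "ses", "task", "acq", "ce", "rec", "dir", "echo",
                    "run")

FUNC_SUFFIXES <- c("bold", "cbv")
ANAT_SUFFIXES <- c("T1w", "T2w")
DWI_SUFFIXES  <- c("dwi")
KNOWN_SUFFIXES <- c(FUNC_SUFFIXES, ANAT_SUFFIXES, DWI_SUFFIXES)

bids_compliance_error <- function(msg) {
  stop(structure(class = c("bids_compliance_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

is_alnum <- function(x) grepl("^[A-Za-z0-9]+$", x)

#' Parse an operator instruction name into BIDS entities
#'
#' Operator "Instruction Name" strings follow the grammar
#' `key-value_key-value_..._suffix`: underscore-separated tokens, each
#' either a `<short identifier>-<alphanumeric value>` pair or, in final
#' position only, a bare modality suffix (e.g. `bold`, `T1w`).  Values
#' must be strictly alphanumeric — underscores and hyphens are the BIDS
#' field separators and cannot appear inside values.
#'
#' @param name instruction-name string (nonempty).
#' @return named list with any of `task`, `acq`, `ce`, `rec`, `dir`,
#'   `echo`, `sub`, `ses` and `suffix` (others `NULL`).  Unknown short
#'   identifiers produce a warning and are ignored; a malformed token
#'   raises a `bids_compliance_error` naming it.
#' @examples
#' parse_instruction_name("acq-seEPI_task-rest_bold")
#' @export
parse_instruction_name <- function(name) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    bids_compliance_error("instruction name must be a nonempty string")
  }
  tokens <- strsplit(name, "_", fixed = TRUE)[[1]]
  out <- list()
  for (i in seq_along(tokens)) {
    tok <- tokens[[i]]
    if (grepl("-", tok, fixed = TRUE)) {
      kv <- strsplit(tok, "-", fixed = TRUE)[[1]]
      if (length(kv) != 2L || !nzchar(kv[1]) || !nzchar(kv[2])) {
        bids_compliance_error(sprintf(
          "token '%s' in '%s' is not a legal key-value pair", tok, name))
      }
      if (!is_alnum(kv[2])) {
        bids_compliance_error(sprintf(
          "value '%s' of token '%s' contains non-alphanumeric characters",
          kv[2], tok))
      }
      if (!kv[1] %in% BIDS_SHORT_IDS) {
        warning(sprintf("unknown BIDS short identifier '%s' in '%s'; token ignored",
                        kv[1], name), call. = FALSE)
        next
      }
      out[[kv[1]]] <- kv[2]
    } else if (i == length(tokens)) {
      if (!is_alnum(tok)) {
        bids_compliance_error(sprintf(
          "suffix token '%s' contains non-alphanumeric characters", tok))
      }
      out$suffix <- tok
    } else {
      # bare token before suffix position: no tokenization of the name is a
      # legal entity sequence (e.g. an underscore splitting a value)
      bids_compliance_error(sprintf(
        "bare token '%s' in '%s' outside suffix position (underscore inside a value?)",
        tok, name))
    }
  }
  out
}

#' Extract subject and session identifiers from a subject file
#'
#' The ParaVision `subject` file carries the operator "Animal ID"
#' (`SUBJECT_id`, the BIDS subject) and "Study Name" (`SUBJECT_study_name`,
#' the BIDS session).  Identity is never read from the directory name.
#'
#' @param subject_file a `ParameterDict` from the study's `subject` file.
#' @return list with `subject` and `session` strings.
#' @export
extract_subject_session <- function(subject_file) {
  src <- subject_file$source_path
  loc <- if (is.na(src)) "subject file" else src
  out <- list()
  for (spec in list(c("SUBJECT_id", "subject"),
                    c("SUBJECT_study_name", "session"))) {
    val <- pv_param(subject_file, spec[1], default = NULL)
    if (is.null(val)) {
      bids_compliance_error(sprintf("%s: missing key %s", loc, spec[1]))
    }
    val <- as.character(val)[1]
    if (!is_alnum(val)) {
      bids_compliance_error(sprintf(
        "%s: %s value '%s' is not alphanumeric; redress the study (edit the line below ##$%s=) before converting",
        loc, spec[1], val, spec[1]))
    }
    out[[spec[2]]] <- val
  }
  out
}

#' Infer the modality suffix from the sequence name
#'
#' An explicit operator suffix always wins.  Otherwise FLASH-family
#' (gradient-echo) sequences are assigned `T1w` and RARE/TurboRARE-family
#' (spin-echo) sequences `T2w`.  A scan whose suffix stays undetermined is
#' excluded from conversion with a logged reason (returned suffix `NA`).
#'
#' @param sequence_name sequence/method name from `acqp`.
#' @param entities partial entity list (possibly lacking `suffix`).
#' @return `entities` with `suffix` filled in, or `NA` suffix when
#'   undetermined.
#' @export
infer_modality_suffix <- function(sequence_name, entities) {
  if (!is.null(entities$suffix) && !is.na(entities$suffix)) return(entities)
  sq <- if (is.null(sequence_name)) NA_character_ else sequence_name
  entities$suffix <-
    if (!is.na(sq) && grepl("FLASH", sq, ignore.case = TRUE)) "T1w"
    else if (!is.na(sq) && grepl("RARE", sq, ignore.case = TRUE)) "T2w"
    else NA_character_
  entities
}

suffix_category <- function(suffix) {
  if (is.na(suffix)) return(NA_character_)
  if (suffix %in% FUNC_SUFFIXES) "func"
  else if (suffix %in% ANAT_SUFFIXES) "anat"
  else if (suffix %in% DWI_SUFFIXES) "dwi"
  else NA_character_
}

#' Build the candidate-scan metadata table for a study collection
#'
#' One row per scan with a determinable modality suffix; the debuggable
#' work-directory record.  Non-compliant studies (bad subject file or
#' instruction names) are skipped whole-study or per-scan with a warning,
#' never converted partially wrong.
#'
#' @param studies list of `StudyDirectory` objects (or a single one).
#' @return data.frame (`MetadataTable`) with columns `study_path`,
#'   `scan_number`, `scan_path`, `subject`, `session`, `task`, `acq`,
#'   `suffix`, `category`, `acq_time`, `repetition_time`.  `run` is added
#'   by [assign_run_numbers()].
#' @export
build_metadata_table <- function(studies) {
  if (inherits(studies, "StudyDirectory")) studies <- list(studies)
  rows <- list()
  for (st in studies) {
    ids <- tryCatch(extract_subject_session(st$subject_file),
                    bids_compliance_error = function(e) {
                      warning(sprintf("study %s skipped: %s",
                                      st$directory_name, conditionMessage(e)),
                              call. = FALSE)
                      NULL
                    })
    if (is.null(ids)) next
    for (scan in st$scans) {
      ents <- tryCatch(parse_instruction_name(scan$instruction_name),
                       bids_compliance_error = function(e) {
                         warning(sprintf("scan %d in %s skipped: %s",
                                         scan$scan_number, st$directory_name,
                                         conditionMessage(e)), call. = FALSE)
                         NULL
                       })
      if (is.null(ents)) next
      ents <- infer_modality_suffix(scan$sequence_name, ents)
      if (is.na(ents$suffix)) {
        message(sprintf("scan %d in %s: modality suffix undetermined; excluded",
                        scan$scan_number, st$directory_name))
        next
      }
      category <- suffix_category(ents$suffix)
      if (is.na(category)) {
        message(sprintf("scan %d in %s: unsupported suffix '%s'; excluded",
                        scan$scan_number, st$directory_name, ents$suffix))
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        study_path = st$path,
        scan_number = scan$scan_number,
        scan_path = scan$scan_path,
        subject = ids$subject,
        session = ids$session,
        task = ents$task %||% NA_character_,
        acq = ents$acq %||% NA_character_,
        suffix = ents$suffix,
        category = category,
        acq_time = ifelse(is.na(st$timestamp), NA_character_,
                          format(st$timestamp, "%Y-%m-%dT%H:%M:%S")),
        repetition_time = scan$repetition_time,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L) return(empty_metadata_table())
  do.call(rbind, rows)
}

empty_metadata_table <- function() {
  data.frame(study_path = character(), scan_number = integer(),
             scan_path = character(), subject = character(),
             session = character(), task = character(), acq = character(),
             suffix = character(), category = character(),
             acq_time = character(), repetition_time = numeric(),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assign run ordinal numbers
#'
#' Within each (subject, session, task, acq, suffix) group, scans sorted
#' by ascending scan number receive consecutive run indices starting at
#' `base` (default 0; singleton groups also get a run entity so that
#' output names are uniform and glob-friendly).
#'
#' @param rows a `MetadataTable`.
#' @param base first run index, 0 (default) or 1.
#' @return `rows` with a `run` integer column, original row order kept.
#' @export
assign_run_numbers <- function(rows, base = 0L) {
  stopifnot(base %in% c(0L, 1L))
  if (nrow(rows) == 0L) {
    rows$run <- integer(0)
    return(rows)
  }
  rows$run <- NA_integer_
  key <- paste(rows$subject, rows$session, rows$task, rows$acq, rows$suffix,
               sep = "\r")
  for (k in unique(key)) {
    idx <- which(key == k)
    idx <- idx[order(rows$scan_number[idx])]
    rows$run[idx] <- seq_along(idx) - 1L + as.integer(base)
  }
  rows
}

#' Construct a scan selector
#'
#' A selector is a dictionary mapping BIDS field names to lists of
#' accepted value strings, e.g. `scan_selector(acquisition = "EPI")`
#' categorizes every scan whose acquisition entity contains "EPI" as a
#' substring.
#'
#' @param ... named character vectors; accepted names: `acquisition`,
#'   `task`, `subject`, `session`, `suffix`.
#' @return object of class `ScanSelector`.
#' @export
scan_selector <- function(...) {
  criteria <- list(...)
  if (length(criteria) == 1L && is.null(names(criteria)) &&
      is.list(criteria[[1]])) {
    criteria <- criteria[[1]]
  }
  known <- c(acquisition = "acq", task = "task", subject = "subject",
             session = "session", suffix = "suffix")
  bad <- setdiff(names(criteria), names(known))
  if (length(bad) > 0L || is.null(names(criteria)) ||
      any(!nzchar(names(criteria)))) {
    stop(sprintf("unknown selector field(s): %s (known: %s)",
                 paste(bad, collapse = ", "),
                 paste(names(known), collapse = ", ")), call. = FALSE)
  }
  structure(lapply(criteria, as.character), class = "ScanSelector")
}

#' Select scans matching a selector, labelling them with a category
#'
#' A row matches when, for every selector field, the row's value contains
#' at least one of the accepted strings as a substring (case-sensitive;
#' "EPI" selects `seEPI`).  Rows with a missing value for a selector field
#' never match.
#'
#' @param rows a `MetadataTable`.
#' @param selector a [scan_selector()].
#' @param category one of `"anat"`, `"func"`, `"dwi"`.
#' @return the matching rows, with `category` overwritten.
#' @export
select_scans <- function(rows, selector, category) {
  stopifnot(inherits(selector, "ScanSelector"),
            category %in% c("anat", "func", "dwi"))
  if (length(selector) == 0L) {
    stop("selector must be nonempty for the category to be produced",
         call. = FALSE)
  }
  field_map <- c(acquisition = "acq", task = "task", subject = "subject",
                 session = "session", suffix = "suffix")
  keep <- rep(TRUE, nrow(rows))
  for (fld in names(selector)) {
    col <- rows[[field_map[[fld]]]]
    accepted <- selector[[fld]]
    hit <- rep(FALSE, length(col))
    for (a in accepted) hit <- hit | grepl(a, col, fixed = TRUE)
    keep <- keep & hit & !is.na(col)
  }
  out <- rows[keep, , drop = FALSE]
  if (nrow(out) > 0L) out$category <- category
  rownames(out) <- NULL
  out
}

#' Write the metadata table to the work directory
#'
#' @param rows a `MetadataTable`.
#' @param workdir directory (created if needed).
#' @param name file name.
#' @return the path, invisibly.
#' @export
write_metadata_table <- function(rows, workdir, name = "metadata.tsv") {
  dir.create(workdir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(workdir, name)
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
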