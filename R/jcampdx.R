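#' Parse a ParaVision parameter file
#'
#' ParaVision (PV 6.x) stores acquisition metadata in plain-text files
#' (`subject`, `acqp`, `method`, `visu_pars`) written in a JCAMP-DX-like
#' dialect: each parameter is introduced by a line `##$KEY=...`, comment
#' lines start with `$$`, and non-`$` header lines start with `##`.
#' A value given on the `##$KEY=` line itself is a scalar; a size header
#' of the form `( n )` or `( n, m )` announces that the value follows on
#' the next line(s), which are concatenated (single spaces) until the next
#' `##` or `$$` line and then tokenized.  `<...>` spans are strings and are
#' stored with the angle-bracket delimiters stripped; whitespace-separated
#' numerals become numeric vectors.
#'
#' @param text character scalar (raw file content) or character vector of
#'   lines.
#' @param source_path optional path recorded on the result for diagnostics.
#' @return An object of class `ParameterDict`: a list with elements
#'   `entries` (named list, parameter name to scalar/vector value),
#'   `headers` (named list of uninterpreted non-`$` `##` header lines, kept
#'   verbatim for debugging) and `source_path`.
#' @examples
#' pd <- parse_parameter_file("##$SUBJECT_id=( 60 )\n<Mc365A>")
#' pd$entries$SUBJECT_id  # "Mc365A"
#' @export
parse_parameter_file <- function(text, source_path = NA_character_) {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    lines <- as.character(text)
  }
  lines <- sub("[ \t\r]+$", "", lines)

  entries <- list()
  headers <- list()
  n <- length(lines)
  i <- 1L
  while (i <= n) {
    line <- lines[[i]]
    if (!nzchar(line) || startsWith(line, "$$")) {
      i <- i + 1L
      next
    }
    if (startsWith(line, "##$")) {
      eq <- regexpr("=", line, fixed = TRUE)
      if (eq < 0L) {
        stop(sprintf("line %d: parameter line without '=': %s", i, line),
             call. = FALSE)
      }
      key <- substr(line, 4L, eq - 1L)
      if (key %in% names(entries)) {
        stop(sprintf("line %d: duplicate parameter key '%s'", i, key),
             call. = FALSE)
      }
      rhs <- substr(line, eq + 1L, nchar(line))
      if (grepl("^\\s*\\(", rhs)) {
        # size header: value lives on the following continuation lines
        if (!grepl("^\\s*\\(\\s*[0-9]+(\\s*,\\s*[0-9]+)*\\s*\\)\\s*$", rhs)) {
          stop(sprintf("line %d: malformed array size header '%s' for key '%s'",
                       i, rhs, key), call. = FALSE)
        }
        j <- i + 1L
        cont <- character()
        while (j <= n && !startsWith(lines[[j]], "##") &&
               !startsWith(lines[[j]], "$$")) {
          cont <- c(cont, lines[[j]])
          j <- j + 1L
        }
        entries[[key]] <- pv_tokenize(paste(trimws(cont), collapse = " "))
        i <- j
      } else {
        entries[[key]] <- pv_tokenize(trimws(rhs))
        i <- i + 1L
      }
    } else if (startsWith(line, "##")) {
      eq <- regexpr("=", line, fixed = TRUE)
      key <- if (eq > 0L) substr(line, 3L, eq - 1L) else substr(line, 3L, nchar(line))
      val <- if (eq > 0L) substr(line, eq + 1L, nchar(line)) else ""
      headers[[key]] <- val
      i <- i + 1L
    } else {
      # stray continuation outside any parameter: ignore (lossless parsers
      # would attach it, but PV never emits this outside array bodies)
      i <- i + 1L
    }
  }
  structure(list(entries = entries, headers = headers,
                 source_path = source_path),
            class = "ParameterDict")
}

#' Read a ParaVision parameter file from disk
#'
#' @param path file path.
#' @return A [parse_parameter_file()] `ParameterDict`.
#' @export
read_parameter_file <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("parameter file does not exist: %s", path), call. = FALSE)
  }
  parse_parameter_file(readLines(path, warn = FALSE), source_path = path)
}

# Tokenize one logical (already joined) parameter value.
# <...> spans -> strings (delimiters stripped, may contain spaces);
# otherwise whitespace-separated tokens, all-numeric -> numeric vector.
pv_tokenize <- function(s) {
  if (!nzchar(s)) return("")
  if (grepl("<", s, fixed = TRUE)) {
    m <- gregexpr("<[^>]*>", s)[[1]]
    toks <- regmatches(s, gregexpr("<[^>]*>", s))[[1]]
    vals <- substr(toks, 2L, nchar(toks) - 1L)
    if (length(vals) == 1L) return(vals)
    return(vals)
  }
  toks <- strsplit(s, "[ \t]+")[[1]]
  toks <- toks[nzchar(toks)]
  if (length(toks) == 0L) return("")
  num <- suppressWarnings(as.numeric(toks))
  if (!anyNA(num)) {
    if (length(num) == 1L) return(num)
    return(num)
  }
  if (length(toks) == 1L) return(toks)
  toks
}

#' Look up a parameter with an optional default
#'
#' @param pd a `ParameterDict`.
#' @param key parameter name (without the `##$` prefix).
#' @param default value returned when the key is absent.
#' @return the stored value, or `default`.
#' @export
pv_param <- function(pd, key, default = NULL) {
  stopifnot(inherits(pd, "ParameterDict"))
  if (key %in% names(pd$entries)) pd$entries[[key]] else default
}

#' @export
print.ParameterDict <- function(x, ...) {
  cat(sprintf("<ParameterDict: %d parameters, %d headers (%s)>\n",
              length(x$entries), length(x$headers),
              ifelse(is.na(x$source_path), "in-memory", x$source_path)))
  invisible(x)
}

# Serialize entries back into the dialect parse_parameter_file() reads.
# Numeric/string vectors of length > 1 (and any value passed wrapped in
# pv_array()) are written with a ( n ) size header; strings get <...>.
# Numeric arrays wrap at ~70 chars to exercise continuation-line joining.
format_parameter_file <- function(entries, title = "Parameter List") {
  out <- c(sprintf("##TITLE=%s", title),
           "##JCAMPDX=4.24",
           "$$ written by bru2bids fixture writer")
  for (key in names(entries)) {
    val <- entries[[key]]
    if (is.character(val)) {
      body <- paste0("<", val, ">")
      if (length(val) == 1L) {
        out <- c(out, sprintf("##$%s=( %d )", key, nchar(val)), body)
      } else {
        out <- c(out, sprintf("##$%s=( %d )", key, length(val)),
                 paste(body, collapse = " "))
      }
    } else if (length(val) == 1L) {
      out <- c(out, sprintf("##$%s=%s", key, format(val, scientific = FALSE)))
    } else {
      toks <- format(val, scientific = FALSE, trim = TRUE)
      wrapped <- character()
      cur <- ""
      for (tk in toks) {
        cand <- if (nzchar(cur)) paste(cur, tk) else tk
        if (nchar(cand) > 70L) {
          wrapped <- c(wrapped, cur)
          cur <- tk
        } else {
          cur <- cand
        }
      }
      wrapped <- c(wrapped, cur)
      out <- c(out, sprintf("##$%s=( %d )", key, length(val)), wrapped)
    }
  }
  c(out, "##END=")
}
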