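# Shared fixture builders and independent oracles.

`%||%` <- function(a, b) if (is.null(a)) b else a

# A typical compliant study: two functional runs (2D multi-frame EPI)
# plus one structural scan (3D RARE without an operator suffix, so the
# T2w inference path is exercised).
default_scan_specs <- function() {
  list(
    fixture_scan_spec(5L, "acq-seEPI_task-rest_bold",
                      sequence_name = "Bruker:EPI",
                      matrix_size = c(8L, 8L), n_slices = 4L,
                      n_timepoints = 3L, slope = 2.5, tr_ms = 1500,
                      te_ms = 15),
    fixture_scan_spec(6L, "acq-TurboRARE",
                      sequence_name = "Bruker:TurboRARE",
                      matrix_size = c(8L, 8L, 4L), tr_ms = 4000,
                      te_ms = 36),
    fixture_scan_spec(7L, "acq-seEPI_task-rest_bold",
                      sequence_name = "Bruker:EPI",
                      matrix_size = c(8L, 8L), n_slices = 4L,
                      n_timepoints = 3L, slope = 2.5, tr_ms = 1500,
                      te_ms = 15)
  )
}

make_study <- function(dir, subject = "Mc365A", session = "R02",
                       scans = default_scan_specs(), seed = 1L, ...) {
  generate_study(fixture_study_spec(subject = subject, session = session,
                                    scans = scans, ...),
                 dir, seed = seed)
}

# Single-purpose reference parser for the spec's ACQ_size-style fixtures:
# handles only `##$KEY=( n )` followed by exactly one numeric line.
# Written independently of parse_parameter_file to serve as its oracle.
reference_parse_numeric_array <- function(lines) {
  out <- list()
  for (i in seq_along(lines)) {
    if (grepl("^##\\$[A-Za-z_]+=\\( [0-9]+ \\)$", lines[i])) {
      key <- sub("^##\\$([A-Za-z_]+)=.*$", "\\1", lines[i])
      out[[key]] <- as.numeric(strsplit(trimws(lines[i + 1]), " +")[[1]])
    }
  }
  out
}

# entity extraction from an emitted BIDS filename (oracle for recovery
# tests: regex over the name, not compose_bids_path in reverse)
filename_entities <- function(path) {
  base <- basename(path)
  base <- sub("\\.nii(\\.gz)?$", "", base)
  toks <- strsplit(base, "_", fixed = TRUE)[[1]]
  ents <- list(suffix = toks[length(toks)])
  for (tok in toks[-length(toks)]) {
    kv <- strsplit(tok, "-", fixed = TRUE)[[1]]
    ents[[kv[1]]] <- paste(kv[-1], collapse = "-")
  }
  ents$category <- basename(dirname(path))
  ents
}

# recursive file digest of a directory tree (byte-identity comparisons)
tree_digest <- function(root) {
  files <- sort(list.files(root, recursive = TRUE, all.files = TRUE,
                           no.. = TRUE))
  vapply(files, function(f) {
    unname(tools::md5sum(file.path(root, f)))
  }, "")
}
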