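test_that("instruction names parse into entities", {
  e <- parse_instruction_name("acq-seEPI_task-rest_bold")
  expect_identical(e$acq, "seEPI")
  expect_identical(e$task, "rest")
  expect_identical(e$suffix, "bold")

  expect_identical(parse_instruction_name("bold"), list(suffix = "bold"))

  # underscore inside a value splits the token; "se" stranded mid-name
  expect_error(parse_instruction_name("acq-se_EPI_bold"),
               class = "bids_compliance_error")
  expect_error(parse_instruction_name("task-re st_bold"),
               class = "bids_compliance_error")
  expect_warning(e <- parse_instruction_name("xyz-foo_bold"),
                 "unknown BIDS short identifier")
  expect_identical(e, list(suffix = "bold"))
})

test_that("subject/session extraction validates alphanumerics", {
  pd <- parse_parameter_file(
    "##$SUBJECT_id=( 60 )\n<Mc365A>\n##$SUBJECT_study_name=( 60 )\n<R02>")
  expect_identical(extract_subject_session(pd),
                   list(subject = "Mc365A", session = "R02"))

  pd2 <- parse_parameter_file(
    "##$SUBJECT_id=( 60 )\n<Mc285AB>\n##$SUBJECT_study_name=( 60 )\n<P02>")
  expect_identical(extract_subject_session(pd2),
                   list(subject = "Mc285AB", session = "P02"))

  bad <- parse_parameter_file(
    "##$SUBJECT_id=( 60 )\n<Mc_365>\n##$SUBJECT_study_name=( 60 )\n<R02>")
  expect_error(extract_subject_session(bad),
               class = "bids_compliance_error")
  missing <- parse_parameter_file("##$SUBJECT_id=( 60 )\n<A>")
  expect_error(extract_subject_session(missing),
               class = "bids_compliance_error")
})

test_that("modality suffix inference: FLASH -> T1w, RARE -> T2w, explicit wins", {
  expect_identical(infer_modality_suffix("FLASH", list())$suffix, "T1w")
  expect_identical(infer_modality_suffix("TurboRARE", list())$suffix, "T2w")
  expect_identical(infer_modality_suffix("FLASH", list(suffix = "T2w"))$suffix,
                   "T2w")
  expect_true(is.na(infer_modality_suffix("UTE", list())$suffix))
})

test_that("run numbers: per-group ordinals by scan number, zero-based", {
  rows <- data.frame(
    subject = "a", session = "s", task = "rest", acq = "seEPI",
    suffix = "bold", scan_number = c(9L, 7L, 3L),
    stringsAsFactors = FALSE)
  rows$acq[3] <- "other"
  out <- assign_run_numbers(rows)
  # brute-force oracle: sort each group and enumerate
  expect_identical(out$run[out$scan_number == 7L], 0L)
  expect_identical(out$run[out$scan_number == 9L], 1L)
  expect_identical(out$run[out$scan_number == 3L], 0L)  # singleton group

  expect_identical(assign_run_numbers(rows, base = 1L)$run[
    rows$scan_number == 7L], 1L)
  empty <- assign_run_numbers(bru2bids:::empty_metadata_table())
  expect_identical(nrow(empty), 0L)
})

test_that("selectors match by substring over every field", {
  rows <- data.frame(
    subject = "a", session = "s", task = "rest",
    acq = c("seEPI", "TurboRARE", "flashEPI"),
    suffix = "bold", category = "func", stringsAsFactors = FALSE)
  sel <- scan_selector(acquisition = c("EPI", "epi"))
  hit <- select_scans(rows, sel, "func")
  # brute-force substring oracle
  manual <- vapply(rows$acq, function(a) {
    any(vapply(c("EPI", "epi"), grepl, TRUE, x = a, fixed = TRUE))
  }, TRUE)
  expect_identical(hit$acq, rows$acq[manual])
  expect_identical(nrow(hit), 2L)

  expect_identical(
    nrow(select_scans(rows[1, ], scan_selector(acquisition = "TurboRARE"),
                      "anat")), 0L)
  expect_error(scan_selector(modality = "x"), "unknown selector field")
  expect_error(select_scans(rows, structure(list(), class = "ScanSelector"),
                            "func"), "nonempty")
})

test_that("extraction is idempotent and selector partition holds", {
  dir <- withr::local_tempdir()
  st <- make_study(dir)
  loaded <- load_study(st$path)
  t1 <- build_metadata_table(loaded)
  t2 <- build_metadata_table(load_study(st$path))
  expect_identical(t1, t2)

  f <- select_scans(t1, scan_selector(acquisition = "seEPI"), "func")
  a <- select_scans(t1, scan_selector(acquisition = "TurboRARE"), "anat")
  expect_identical(intersect(paste(f$study_path, f$scan_number),
                             paste(a$study_path, a$scan_number)),
                   character())
  expect_lte(nrow(f) + nrow(a), nrow(t1))
})

test_that("non-compliant studies and scans are skipped with warnings", {
  dir <- withr::local_tempdir()
  st <- make_study(dir, subject = "Mc_365")
  expect_warning(tab <- build_metadata_table(load_study(st$path)),
                 "skipped")
  expect_identical(nrow(tab), 0L)

  st2 <- make_study(dir, scans = list(
    fixture_scan_spec(1L, "free text name", sequence_name = "Bruker:EPI"),
    fixture_scan_spec(2L, "acq-ok_bold", sequence_name = "Bruker:EPI")))
  expect_warning(tab2 <- build_metadata_table(load_study(st2$path)),
                 "skipped")
  expect_identical(tab2$scan_number, 2L)
})
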