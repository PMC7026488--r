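make_noncompliant_study <- function(dir) {
  make_study(dir, subject = "MD1704", session = "P 02", scans = list(
    fixture_scan_spec(5L, "T2 anatomy scan", sequence_name = "Bruker:RARE",
                      tr_ms = 4000),
    fixture_scan_spec(7L, "bold run (morning)", sequence_name = "Bruker:EPI",
                      matrix_size = c(8L, 8L), n_slices = 4L,
                      n_timepoints = 3L, tr_ms = 1500)),
    timestamp = as.POSIXct("2017-10-24 16:52:48", tz = "UTC"))
}

test_that("subject redress edits exactly the two value lines", {
  dir <- withr::local_tempdir()
  st <- make_noncompliant_study(dir)
  before <- readLines(file.path(st$path, "subject"))
  res <- redress_subject_file(st$path, "Mc285AB", "P02")
  after <- readLines(file.path(st$path, "subject"))
  expect_identical(res$changed, 2L)
  expect_identical(sum(before != after), 2L)
  expect_identical(after[grep("##\\$SUBJECT_id=", after) + 1L], "<Mc285AB>")
  expect_identical(after[grep("##\\$SUBJECT_study_name=", after) + 1L],
                   "<P02>")
  expect_identical(sum(grepl("^-[^-]", res$diff)), 2L)  # minus the --- header
  expect_identical(sum(grepl("^\\+[^+]", res$diff)), 2L)
  expect_true(file.exists(file.path(st$path, "subject.orig")))

  # idempotence: same values again -> empty diff, file untouched
  res2 <- redress_subject_file(st$path, "Mc285AB", "P02")
  expect_identical(res2$changed, 0L)
  expect_length(res2$diff, 0L)
})

test_that("illegal identifiers are refused before any write", {
  dir <- withr::local_tempdir()
  st <- make_noncompliant_study(dir)
  before <- readLines(file.path(st$path, "subject"))
  expect_error(redress_subject_file(st$path, "a_b", "P02"), "refused")
  expect_identical(readLines(file.path(st$path, "subject")), before)
})

test_that("scan program redress changes one line per rename, errors on unknown scans", {
  dir <- withr::local_tempdir()
  st <- make_noncompliant_study(dir)
  sp_path <- file.path(st$path, "ScanProgram.scanProgram")
  before <- readLines(sp_path)
  res <- redress_scan_program(st$path, list(
    "5" = "acq-TurboRARE_T2w",
    "7" = "acq-seEPI_task-rest_bold"))
  after <- readLines(sp_path)
  expect_identical(res$changed, 2L)
  expect_identical(sum(before != after), 2L)
  df <- parse_scan_program(after)
  expect_identical(df$instruction_name,
                   c("acq-TurboRARE_T2w", "acq-seEPI_task-rest_bold"))

  expect_error(redress_scan_program(st$path, list("99" = "bold")),
               "no scan program line.*99")
  # illegal new name refused by the entity grammar before writing
  expect_error(redress_scan_program(st$path, list("5" = "a b_bold")),
               class = "bids_compliance_error")
})

test_that("preview renders an applyable patch and modifies nothing", {
  dir <- withr::local_tempdir()
  st <- make_noncompliant_study(dir)
  plan <- redress_plan(st$path, subject = "Mc285AB", session = "P02",
                       scan_renames = list("5" = "acq-TurboRARE_T2w",
                                           "7" = "acq-seEPI_task-rest_bold"))
  patch_lines <- preview_redress(plan)
  sub_before <- readLines(file.path(st$path, "subject"))
  expect_identical(readLines(file.path(st$path, "subject")), sub_before)

  # oracle: applying the previewed patch with the standard patch tool
  # must reproduce apply_redress() byte for byte
  patched_copy <- file.path(dir, "patched")
  dir.create(patched_copy)
  file.copy(file.path(st$path, c("subject", "ScanProgram.scanProgram")),
            patched_copy)
  patch_file <- file.path(dir, "redress.patch")
  writeLines(patch_lines, patch_file)
  status <- system2("patch", c("-p0", "-d", patched_copy),
                    stdin = patch_file, stdout = FALSE)
  expect_identical(status, 0L)

  apply_redress(plan, backup = FALSE)
  expect_identical(readLines(file.path(patched_copy, "subject")),
                   readLines(file.path(st$path, "subject")))
  expect_identical(
    readLines(file.path(patched_copy, "ScanProgram.scanProgram")),
    readLines(file.path(st$path, "ScanProgram.scanProgram")))

  # no-op plan -> empty patch; missing study -> error
  expect_length(preview_redress(redress_plan(st$path)), 0L)
  expect_error(preview_redress(redress_plan(file.path(dir, "nope"),
                                            subject = "A")),
               "no such study")
})

test_that("redress-then-convert equals a natively compliant conversion", {
  dir <- withr::local_tempdir()
  st <- make_noncompliant_study(file.path(dir, "bad"))
  apply_redress(redress_plan(st$path, subject = "Mc285AB", session = "P02",
                             scan_renames = list(
                               "5" = "acq-TurboRARE_T2w",
                               "7" = "acq-seEPI_task-rest_bold")),
                backup = FALSE)
  native <- make_study(file.path(dir, "good"), subject = "Mc285AB",
                       session = "P02", scans = list(
    fixture_scan_spec(5L, "acq-TurboRARE_T2w", sequence_name = "Bruker:RARE",
                      tr_ms = 4000),
    fixture_scan_spec(7L, "acq-seEPI_task-rest_bold",
                      sequence_name = "Bruker:EPI",
                      matrix_size = c(8L, 8L), n_slices = 4L,
                      n_timepoints = 3L, tr_ms = 1500)),
    timestamp = as.POSIXct("2017-10-24 16:52:48", tz = "UTC"))

  out1 <- file.path(dir, "bids_redressed")
  out2 <- file.path(dir, "bids_native")
  sel <- list(functional_match = scan_selector(acquisition = "EPI"),
              structural_match = scan_selector(acquisition = "TurboRARE"))
  r1 <- do.call(bru2bids, c(list(file.path(dir, "bad"), out1), sel))
  r2 <- do.call(bru2bids, c(list(file.path(dir, "good"), out2), sel))
  expect_identical(r1$status, 0L)
  expect_identical(r2$status, 0L)
  # same seed, same entities: subject subtrees byte-identical
  expect_identical(tree_digest(file.path(out1, "sub-Mc285AB")),
                   tree_digest(file.path(out2, "sub-Mc285AB")))
})
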