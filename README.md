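# bru2bids

Convert small-animal MRI studies from the Bruker ParaVision on-disk layout
into [BIDS](https://bids-specification.readthedocs.io/) datasets.

## The problem

The large majority of small-animal MRI data is acquired with Bruker scanners
running ParaVision (6.x). A ParaVision study is a directory of plain-text
parameter files (`subject`, `acqp`, `method`, `visu_pars`, in a JCAMP-DX-like
`##$KEY=value` dialect) plus a binary volumetric reconstruction (`2dseq`):
transparent, but incompatible with modern neuroimaging pipelines, and its
metadata comes from free-field operator input that differs between labs and
operators. BIDS — a fixed directory hierarchy of NIfTI images with key-value
entities (`sub`, `ses`, `task`, `acq`, `run`) in the filenames and JSON
sidecar metadata — is the community standard those pipelines expect.

This package automates the transition:

- **JCAMP-DX parsing** of all ParaVision parameter files, including
  `( n )`-sized, line-wrapped array values and `<...>` strings.
- **Entity extraction** from operator input: the "Instruction Name" grammar
  `acq-seEPI_task-rest_bold` (underscore-separated `key-value` pairs, a bare
  modality suffix last, values strictly alphanumeric), subject and session
  from the `subject` file (never from the directory name), modality-suffix
  inference (FLASH → `T1w`, TurboRARE/RARE → `T2w`), automatic zero-based
  `run` ordinals, and selector dictionaries (substring matching, so
  `acquisition=EPI` categorizes `acq-seEPI` scans as functional).
- **2dseq → NIfTI conversion**: native decoding of the raw frame stream
  (16/32-bit signed int, unsigned byte, 32-bit float, either byte order,
  per-frame slope/offset scaling) and a native NIfTI-1 writer with the affine
  built from `visu_pars` geometry and the repetition time in the 4D header.
- **BIDS emission**: hierarchy, sidecar JSON (canonical units, vendor fields
  namespaced under `BrukerParaVision`), empty `*_events.tsv` stubs for
  functional scans, per-subject `sessions.tsv` with acquisition onsets parsed
  from the `YYYYMMDD_HHMMSS_*` directory name, `dataset_description.json`,
  `participants.tsv`, and an internal naming validator.
- **Redress**: the retroactive-compliance procedure for preexisting
  non-compliant studies — replace the value line below `##$SUBJECT_id=` /
  `##$SUBJECT_study_name=` and the instruction-name span on `<displayName>`
  lines, as pure line surgery with a unified-diff preview (a full
  subject+session+two-scan redress touches exactly four lines).
- **Fixture generation**: deterministic synthetic multi-species ParaVision
  collections with known ground truth, so the entire pipeline is testable
  without any scanner data.

## Worked example

```r
library(bru2bids)

# synthetic stand-in for a scanner archive: mouse, rat and mouse lemur
# studies with disjoint acquisition vocabularies
generate_collection("collection", n_species = 3, seed = 1)

res <- bru2bids("collection", "bids",
                functional_match = scan_selector(acquisition = "EPI"),
                structural_match = scan_selector(acquisition = "TurboRARE"))
#> converted 5 scan(s) into bids; consider checking the result with the
#> external BIDS validator (https://bids-standard.github.io/bids-validator/)

res$converted[, c("subject", "session", "acq", "suffix", "run", "bids_path")]
#>        subject session       acq suffix run
#> anat      4001    ses1 TurboRARE    T2w   0
#> func.1    4001    ses1     seEPI   bold   0
#> func.2    4001    ses1     seEPI   bold   1
#> func.3      21      r1     geEPI   bold   0
#> func.4      21      r1     geEPI   bold   1
#>                                                                             bids_path
#> anat           sub-4001/ses-ses1/anat/sub-4001_ses-ses1_acq-TurboRARE_run-0_T2w.nii.gz
#> func.1  sub-4001/ses-ses1/func/sub-4001_ses-ses1_task-rest_acq-seEPI_run-0_bold.nii.gz
#> func.2  sub-4001/ses-ses1/func/sub-4001_ses-ses1_task-rest_acq-seEPI_run-1_bold.nii.gz
#> func.3          sub-21/ses-r1/func/sub-21_ses-r1_task-rest_acq-geEPI_run-0_bold.nii.gz
#> func.4          sub-21/ses-r1/func/sub-21_ses-r1_task-rest_acq-geEPI_run-1_bold.nii.gz

validate_tree("bids")
#> character(0)
```

`acquisition = "EPI"` matched the mouse (`seEPI`) and rat (`geEPI`)
functional scans by substring; `TurboRARE` matched only the mouse structural
scan; the lemur studies (vocabulary `lemGE`/`lemMSME`) were excluded by
design. Each image got a sidecar JSON (`RepetitionTime` in seconds), each
functional run an empty `*_events.tsv`, and each subject a
`sub-*_sessions.tsv` with the acquisition onset.

The same surface is available from the console (the script installs under
`<library>/bru2bids/exec/`):

```sh
bru2bids collection bids --func acquisition=EPI --anat acquisition=TurboRARE
bru2bids redress study_dir --subject Mc285AB --session P02 \
         --rename 5=acq-TurboRARE_T2w --dry-run
bru2bids fixtures collection --species 3 --seed 1
```

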