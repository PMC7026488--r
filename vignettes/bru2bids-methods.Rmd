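---
title: "Repositing Bruker ParaVision data as BIDS: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Repositing Bruker ParaVision data as BIDS: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bru2bids)
```

## The conversion model

A ParaVision (PV 6.x) study couples two information streams. The *data*
stream is the `2dseq` file under each scan's `pdata/1/`: a flat binary
sequence of frames, x varying fastest, whose word type, byte order, matrix,
frame count and per-frame linear scaling are declared by the sibling
`visu_pars` file. The *metadata* stream is free-field operator input spread
over plain-text parameter files: the `subject` file (animal and study
identifiers), `ScanProgram.scanProgram` (per-scan "Instruction Name"), and
per-scan `acqp`/`method` files (sequence, timing).

The pipeline maps these onto BIDS as follows:

- **subject / session** come from `SUBJECT_id` and `SUBJECT_study_name` in
  the `subject` file. They are deliberately *never* read from the study
  directory name: renaming the directory is cosmetic, and treating it as
  authoritative would let a file-manager operation silently change subject
  identity. The directory name contributes only the acquisition onset
  (`YYYYMMDD_HHMMSS_` prefix) for `sessions.tsv`; a non-conforming name
  degrades to an empty `acq_time`, never to a failed conversion.
- **task / acq / suffix** come from the instruction name, written by the
  operator as underscore-separated `key-value` pairs with a bare modality
  suffix last (`acq-seEPI_task-rest_bold`). Values must be strictly
  alphanumeric because `_` and `-` are the BIDS field separators; a violated
  token is a *compliance error* (a typed condition) that skips the scan and
  points the user to the redress procedure rather than guessing an
  interpretation. When the operator omitted the suffix it is inferred only
  in the unambiguous cases — FLASH-family sequences are T1-weighted,
  (Turbo)RARE-family T2-weighted — matched case-insensitively on the `acqp`
  method string; anything else is excluded with a logged reason.
- **run** is assigned automatically: within each (subject, session, task,
  acq, suffix) group, scans ordered by their ParaVision scan number receive
  consecutive ordinals. Indexing is zero-based by default, which follows the
  source convention this tool reproduces rather than the `run-1` habit common
  elsewhere in BIDS; `run_base = 1` switches to one-based. The run entity is
  emitted even for singleton groups so that output names are uniform and
  glob-friendly.
- **categories** (anat / func / dwi) are chosen by *selector dictionaries*:
  each maps a BIDS field to accepted value strings, and a scan matches when
  every field of the selector contains at least one accepted string as a
  case-sensitive substring of the scan's value. Substring (not exact)
  matching is what lets a single `acquisition = "EPI"` selector capture
  `seEPI`, `geEPI` and any other EPI variant an operator chose to record.

The scan program is the primary source of instruction names; if it is
missing or yields no entries, each scan's `acqp` is consulted instead
(`ACQ_scan_name`, which carries the same `name (E<n>)` payload). Both routes
must agree on intact studies, and the test suite asserts table-level
equality between them.

## Parameter-file dialect

ParaVision's parameter files are JCAMP-DX-like rather than JCAMP-DX: the
package parses `##$KEY=` parameters, `( n )`/`( n, m )` array-size headers
with values continued on following lines, `<...>` string spans, `$$`
comments, and retains non-`$` `##` headers uninterpreted. The exact
continuation grammar is not publicly specified, so the fixture *writer*
defines the dialect this package guarantees (wrapped numeric arrays joined
with single spaces before tokenization), and a round-trip property
(`parse(write(d)) == d`) pins the contract. Compound JCAMP data tables and
audit trails are out of scope.

## 2dseq decoding and NIfTI emission

Supported word types are 16/32-bit signed integers, unsigned bytes and
32-bit floats in either byte order. The byte count must equal
`wordsize x matrix x frames` exactly; a mismatch is a hard corrupt-data
error, since silently truncating an image is worse than failing. Frame
layout follows the declaration in `visu_pars`: a 3-element `VisuCoreSize`
means each frame is a volume (frame count = timepoints); a 2-element size
means frames are slices x timepoints with the slice count from
`VisuCoreSlicePacksSlices`, slices varying fastest. Frame counts that do not
factor are rejected — multi-echo or multi-channel frame groups are not
modelled. Per-frame `VisuCoreDataSlope`/`VisuCoreDataOffs` scaling is
applied frame-wise.

By default the scaled values are baked into float32 output, because
downstream tools vary in their support of NIfTI's `scl_` fields; `keep_int`
preserves the raw integers and stores slope/intercept in `scl_slope` /
`scl_inter` instead, which is lossless and smaller but relies on readers
honouring those fields.

The affine is built from `visu_pars` geometry: voxel sizes are
`VisuCoreExtent / VisuCoreSize` (through-plane: `VisuCoreFrameThickness`),
direction cosines are the transpose of the row-major 3x3
`VisuCoreOrientation`, translation is the first `VisuCorePosition` triple.
No axis flipping to a canonical orientation is performed by default —
preserving source geometry is lossless and side-steps the question of which
anatomical convention a given cradle implies; `canonical = TRUE` reorients
to the closest-RAS axis permutation without resampling. Missing geometry
degrades to a diagonal affine with a warning. The NIfTI-1 reader/writer is
implemented natively (348-byte header over a gzip stream, sform carrying
the affine, TR in `pixdim[4]`, units mm/s) since no NIfTI package is
available in the supported dependency set; the test suite cross-checks
written files against Python's nibabel as an independent oracle.

Diffusion scans are converted like the others but their `bval`/`bvec`
gradient tables are emitted as empty placeholder files: the sourcing of
gradient tables from the `method` file is deliberately left unimplemented
rather than guessed.

## Redress

Preexisting studies with uninterpretable operator input are made compliant
by editing at most a handful of lines: the value line *below*
`##$SUBJECT_id=` and `##$SUBJECT_study_name=` in the `subject` file, and the
span between `<displayName>` and the ` (E<n>)` token in the scan program.
The implementation is deliberately line-level text surgery on the raw file,
not parse-and-rewrite: byte-preservation of every untouched line keeps the
files valid for ParaVision itself and makes the change reviewable as a
two-to-four-line patch. New identifiers are validated against the entity
grammar *before* any write; edited files get a `.orig` backup unless
disabled; `preview_redress()` renders the exact unified diff without
writing, and applying that diff with a standard `patch` tool reproduces the
in-place edit byte for byte (asserted in the test suite). Multi-line
subject-identifier values are assumed not to occur (single-line values are
what PV 6.x writes).

## The synthetic fixture generator

`generate_study()` / `generate_collection()` emulate a multi-species
scanner archive: complete study directories with subject file, scan
program, `acqp`, `method`, `visu_pars` and encoded `2dseq` content, fully
deterministic given `(spec, seed)`. The three species carry disjoint
acquisition vocabularies and subject pools — mouse `seEPI`/`TurboRARE`
(the guideline example strings), rat `geEPI`/`RAREst`, lemur
`lemGE`/`lemMSME` — chosen so that a generic `EPI`/`TurboRARE` selection
demonstrates partial matching across species while per-species selectors
split a mixed collection into three disjoint, internally valid BIDS
datasets. Functional fixtures are 2D multi-frame EPI-style scans
(8x8, 4 slices, 5 volumes, TR 1.5 s, slope 2.5), structural fixtures 3D
RARE-style volumes (8x8x4, TR 4 s); arrays are kept at or below
16x16x4x10 so the full suite runs in seconds. Non-compliant variants use
free-text instruction names and underscored subject ids; corruption flags
cover a missing scan program (exercising the `acqp` fallback) and truncated
`2dseq` streams.

What the generator does *not* emulate: real ParaVision version quirks
beyond the PV 6.x dialect described above, oblique orientations varying per
scan, multi-echo frame groups, k-space data, or physiologically plausible
image content (voxels are seeded pseudo-random integers). A green test
therefore establishes the correctness of parsing, entity logic, decoding
arithmetic and emission against this package's own dialect contract — not
compatibility with every archive a scanner may produce.

## Numerical and procedural choices

- Integer round-trips (encode→decode→encode) are bit-exact and asserted as
  such; float comparisons use float32-level tolerances.
- JSON sidecars are written with sorted keys, unlimited float precision and
  vendor pass-through under a single `BrukerParaVision` key, making repeated
  runs byte-identical and diffs meaningful.
- The pipeline iterates categories in a fixed order (structural, functional,
  diffusion) purely for reproducibility of the output tree.
- Exit statuses: 0 clean, 1 internal-validator violations, 2 nothing matched
  any selector (a distinct, non-exceptional outcome), 64 usage error.
- The internal tree validator checks naming grammar, entity order,
  directory placement and sidecar pairing only; full validation is the
  external BIDS validator's job, to which the pipeline points on completion.
- The events-file adjustment step present in the original workflow's
  functional graph depends on an undocumented formula; this package emits
  the documented empty stubs and exposes an `events_hook` callback instead
  of guessing.

## Known limitations

MR spectroscopy data, ParaVision 360, k-space reconstruction, multiple
`pdata` reconstructions (only `pdata/1` is converted), gradient-table
extraction, and Nipype-style parallel execution are out of scope; the
pipeline is sequential, which is adequate at the scale where the work
directory's tabular record remains the debugging tool of choice.
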