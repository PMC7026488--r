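Package: bru2bids
Title: Convert Bruker ParaVision Small-Animal MRI Studies to BIDS
Version: 0.1.0
Authors@R: person("Repo", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Automatically converts small-animal MRI studies from the Bruker
    ParaVision on-disk layout (plain-text JCAMP-DX-style parameter files plus
    binary 2dseq volumetric reconstructions) into BIDS 1.x datasets: NIfTI-1
    images, sidecar JSON metadata, events stubs, sessions tables and the
    standard directory hierarchy. Includes selector-based scan categorization
    (functional, structural, diffusion-weighted), a retroactive-compliance
    editor that patches non-compliant subject and scan-program files in place
    with a unified-diff preview, a lightweight internal BIDS naming validator,
    and a deterministic synthetic ParaVision fixture generator so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
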