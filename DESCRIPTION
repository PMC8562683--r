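Package: m6Ascope
Title: Single-Molecule Imaging Analysis of m6A-Modified Transcripts in Single Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for single-molecule, single-cell quantification of
    N6-methyladenosine (m6A) from multi-round fluorescence imaging. Detects
    diffraction-limited spots by rolling-ball background subtraction, Gaussian
    smoothing, local-maxima search and sub-pixel 2D Gaussian fitting; calls
    modified molecules by two-channel colocalization; aligns imaging rounds on
    fiducial beads by phase cross-correlation; registers the nanowell cell
    occupancy matrix to the flow-cell RNA density matrix by exhaustive 2D
    cross-correlation; decodes sequential FISH rounds into a gene-by-cell
    expression matrix with m6A levels; and designs seqFISH primary and readout
    probes. Includes a seeded forward simulator of the whole experiment so
    every stage is testable without a microscope.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    minpack.lm,
    Rtsne,
    stats,
    utils,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    Biostrings,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
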