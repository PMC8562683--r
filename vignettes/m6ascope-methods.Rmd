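---
title: "Methods: single-molecule single-cell m6A quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-molecule single-cell m6A quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(m6Ascope)
```

## The measurement model

The assay turns m6A detection into counting. PolyA+ transcripts are captured
on an oligo-dT surface and appear as diffraction-limited spots in a molecule
channel (Cy3 3' label); an anti-m6A antibody plus dye-conjugated secondary
marks modified molecules in a second channel. A molecule is called modified
when the two channels' fitted spot centers lie within a colocalization
radius. All downstream quantities are binomial fractions of these calls:

- single-cell m6A level = m6A+ molecules / total molecules in that cell's
  well (`cell_m6a_level()`);
- gene m6A level = m6A+ gene-specific molecules / total gene-specific
  molecules, reported only where the estimate is reliable
  (`gene_m6a_level()`).

Because each call is binary — a molecule either colocalizes or it does not —
the method reads out modification *frequency*, not per-molecule
stoichiometry. That is a deliberate scope limit, and it is why the per-cell
estimator's error shrinks as 1/sqrt(N) in the number of captured molecules.

## Spot detection and localization

`detect_spots()` follows the classical single-molecule chain:

1. **Rolling-ball background subtraction** (`subtract_background()`, radius
   3 px). The background is the grayscale opening of the image with a ball
   structuring element of height `sqrt(r^2 - d^2)`; a diffraction-limited
   spot (PSF sigma ~1.3 px) is too narrow for the ball to climb, so its peak
   survives within a few percent while smooth background is removed exactly.
2. **Gaussian blur** (`smooth_gaussian()`, sigma 1.1 px) to suppress
   single-pixel noise before the maxima search. The kernel is a normalized
   discrete Gaussian with half-width `ceiling(4*sigma)`; borders are
   edge-replicated so constant images pass through unchanged.
3. **Local maxima strictly above a pixel threshold.** The threshold is a
   *predetermined* configuration value. `estimate_threshold()` offers a
   median + 5 MAD estimate as a convenience for sparse fields; on dense
   fields (such as the simulator's well footprints, where spot halos cover a
   large area fraction) the MAD is inflated and an explicit threshold should
   be set from the known intensity scale. Duplicate maxima within 2 px are
   merged to the brighter one.
4. **Sub-pixel 2D Gaussian fit** (`fit_gaussian_2d()`): isotropic Gaussian
   plus constant local background, least squares over a 7 x 7 window
   (half-width 3, covering > 3 sigma for sigma ~1.3 px), solved by
   Levenberg-Marquardt. Non-convergent or out-of-window fits are returned
   flagged (`status = "failed"`), never silently dropped.

Coordinates are 0-based `(row, col)` with the origin at the center of the
top-left pixel; one pixel corresponds to ~100 nm. On noiseless renders the
median localization error is below 0.1 px; at peak SNR around 10 it stays
within the half-pixel accuracy the two-color colocalization needs (the
acceptance suite measures both).

## Colocalization and round alignment

`match_spots()` performs one-to-one matching: all candidate pairs within
`max_dist` are sorted by distance and accepted greedily. The distance
criterion (1 px for modification calling, 2 px for antibody validation) is
the assay's definition; the one-to-one resolution is our choice — greedy
nearest is deterministic, symmetric in the two channels, and cannot double
count a molecule. `detection_metrics()` converts a match into detection
rate, and with ground-truth labels into sensitivity and specificity.

Imaging rounds drift by a few pixels, so fiducial beads imaged in a dedicated
channel anchor every round. `align_rounds()` estimates the rigid translation
by phase cross-correlation (normalized cross-power spectrum, integer peak,
parabolic sub-pixel refinement) and the offset is applied to *spot
coordinates*, never by resampling images, to avoid interpolation artifacts.
A normalized peak below 0.05 raises an alignment error naming the round —
this guards blank or failed rounds rather than silently mis-aligning them.

## Nanowell registration

The low-magnification scan yields a cell occupancy matrix (COM, default
121 x 381 wells) via `detect_cells()` (find-maxima on the nuclear channel,
disk-sampled channel intensities, rectangle gating in `classify_phenotype()`)
and `build_com()`. The flow-cell FOVs yield an RNA density matrix (RDM,
default 31 x 51) of per-well molecule and m6A counts (`build_rdm()`).

`register_rdm_to_com()` scores the Pearson correlation between the RDM and
every same-shape contiguous COM subset — computed for all offsets at once by
FFT cross-correlation with per-offset normalization from summed-area tables,
and validated against a naive per-offset loop (`method = "direct"`), which is
also the fallback whenever FOVs are missing (excluded pairwise rather than
zero-filled). The best offset must be an *outlier* of the correlation map:
we require a z-score of at least 5 against the distribution over all offsets
before linking is allowed. The threshold is configuration-exposed because the
z-score scale depends on the number of candidate offsets; small demonstration
grids (tens of offsets) warrant a laxer value than the full geometry's
~30,000 offsets. Correlation uses raw counts, not binarized occupancy, so
doublet wells contribute signal; only translations are searched (no flips or
rotations), matching the physical transfer of the sealed coverslip.

`link_single_cells()` then emits one record per RDM position whose registered
well holds exactly one cell; empty and doublet wells are excluded. Well
indices are 1-based matrix indices; registration offsets are 0-based, so RDM
entry `(i, j)` maps to COM well `(i + drow, j + dcol)`.

## seqFISH decoding and expression analysis

The 9-gene panel is read out one gene per round (no combinatorial
barcoding), so `decode_seqfish()` counts each round's aligned spots per
linked well and couples them to the pre-hybridization m6A spot map with the
same 1-px colocalization rule. `normalize_expression()` divides gene counts
by each cell's total captured molecules, applies log2 with a pseudocount,
and mean-centers each gene across cells. The pseudocount defaults to
1/total per cell — the smallest nonzero ratio's scale — because the handling
of zeros is otherwise unspecified; it is configuration-exposed.
`qc_cells()` requires at least `min_detect` (default 1) of the housekeeping
genes GAPDH/ENO1/EEF2 detected. `embed_cells()` wraps Rtsne with perplexity
10 and a fixed seed.

The gene-level reliability filter keeps an estimate when gene-specific total
counts are at least 10 *or* log-mean expression is at least 0.02. One display
variant of this rule uses the threshold with the opposite sign (-0.02); the
positive-threshold rule is implemented as the default and the other is
reachable by passing `min_log_mean_expr = -0.02`.

## Probe design

`design_probes()` is a deterministic rule chain: enumerate 25-30 nt windows
on the exon-consensus sense sequence; keep GC within 45-70% inclusive; drop
homopolymer runs of 5 or more; select left-to-right greedily with at least
2 nt between adjacent probe footprints (we read "at least 2-nt distance" as
a footprint gap — the start-to-start reading would allow overlapping
probes); drop any probe sharing a 17-nt-or-longer exact substring (either
strand) with any other probe, the later-scanned probe of a matched pair
being the one dropped; trim sets above 32 probes by removing probes farthest
from 55% GC (ties drop the later start); screen 20-nt readouts against the
transcriptome reference, discarding any with a 15-nt-or-longer exact match;
and assemble each oligo as `revcomp(window) + "TA" + revcomp(readout)` (the
emitted hybridizing strand anneals to the mRNA). Exact-substring matching
deliberately replaces BLAST for the 17-nt and 15-nt rules: at these lengths
an ungapped exact seed is what BLAST would report, and exact matching is
deterministic and dependency-free. Sets outside the 20-32 band are flagged
in the design report, not dropped. `verify_probe_set()` re-checks every rule
independently (all-pairs, both strands) and is used by the tests to prove
the pipeline sound against its own specification.

## The simulator: what it emulates, and what it does not

`simulate_experiment()` is the package's microscope stand-in. It plants:
cells in wells (Poisson loading, rate 0.3/well — dilute loading where most
occupied wells are singlets), two dye phenotypes with distinct mean channel
intensities and distinct m6A fractions (defaults 0.30 and 0.15, a 2-fold
difference), per-cell molecule counts (Poisson, mean 250), per-molecule gene
identities (phenotype-specific multinomial over a 9-gene panel including the
housekeeping trio), spot positions uniform in the FOV's signal square inside
a blank frame (the well-wall footprint, giving the characteristic grid-like
pattern), log-normal spot amplitudes, modified molecules duplicated into the
m6A channel with 0.05-px jitter, fiducial beads at 10x the median spot
amplitude persisting across rounds under recorded per-round drifts, and the
imaged window placed at a recorded offset in the well grid. Images get the
standard CCD model: constant background, Poisson shot noise, Gaussian read
noise (`noise_model()`).

Known departures from real data: no optical aberrations or TIRF
evanescent-field decay, no photobleaching, no non-specific surface binding,
no chromatic offset between channels (alignment is still exercised via the
planted per-round drifts), and simulated FOVs are spatially scaled down
(default 128 x 128 px versus the ~1,200 x 1,200 px a real 15,400-square-µm
well footprint would cover at 100 nm/px) with correspondingly higher spot
density. Passing tests therefore demonstrate correctness of the *algorithms*
under a faithful noise model, not robustness to every optical artifact of a
physical instrument.

Determinism is strict: a `(config, seed)` pair reproduces every image and
table bit-identically, and the planted ground truth is reconciled with what
was actually placeable (rejection sampling enforces a 5-px minimum spot
separation, so extremely dense wells may place fewer molecules than drawn —
the ground-truth tables always record what is really in the images).

## Problem sizes and numerical choices

The test and acceptance runs use scaled-down grids chosen to exercise every
code path while keeping the whole suite interactive: registration
plant-and-recover runs at the full 121 x 381 / 31 x 51 geometry (matrices
only, 50 seeded trials), while image-rendering runs use a 20 x 30 well grid
with a 6 x 9 imaged window, ~220 molecules per cell, and an explicit
detection threshold of 180 counts set from the simulated amplitude scale
(log-normal around 800 counts over a 100-count background). Sub-pixel
localization is characterized over 100 seeded single-spot fields at peak
SNR ~ 10 (amplitude 161 over background 100).

Other numeric decisions: Gaussian fit window 7 x 7; fit parameter box
bounds (sigma in [0.3, 2x window]) with fits pinned to the box flagged as
failures; merge radius 2 px keeping the brighter maximum; correlation
offsets with near-zero window variance scored as missing; matching ties
broken by the symmetric key (distance, min index, max index); t-SNE requires
more than 3 x perplexity + 1 cells and fails with an actionable message
below that.

## Limitations

Registration assumes a rigid translation between scan and flow cell; a
rotated or mirrored coverslip is out of scope (an orientation search would
quadruple the offset space and is not implemented). Phenotype gating is
axis-aligned rectangles, adequate for well-separated stains only. The m6A
call is binary per molecule; modification stoichiometry within a molecule is
not measured. Doublets whose nuclei overlap in the low-magnification scan
can be miscounted as singlets by `detect_cells()`; the occupancy-based
exclusion then cannot catch them, which mirrors the real assay's reliance on
resolvable nuclei.
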