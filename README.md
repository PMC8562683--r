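# m6Ascope

Single-molecule, single-cell quantification of N6-methyladenosine (m6A) from
fluorescence imaging.

## The problem

m6A is the most abundant internal mRNA modification, but bulk assays average
it over millions of cells. An imaging-based route measures it molecule by
molecule: polyA+ transcripts captured on an oligo-dT surface are registered
as diffraction-limited spots in one color (Cy3 3'-labeling), and m6A-modified
molecules are marked in a second color by an anti-m6A antibody/secondary
complex. A molecule whose two-channel spot centers colocalize within ~1 pixel
(~100 nm) scores as modified, so the m6A level of any pool of molecules is a
simple counting ratio. Loading cells into a nanowell array before lysis
extends this to single cells: a low-magnification scan counts and phenotypes
the cells per well, the lysate's molecules are imaged per well on the flow
cell, and the two grids are re-linked computationally. Sequential FISH rounds
over the same surface then add per-gene counts for the same cells.

`m6Ascope` implements the computational side of this workflow end to end,
plus a seeded forward simulator of the microscope so every stage can be
validated against planted ground truth:

- **Spot detection** — rolling-ball background subtraction (radius 3 px),
  Gaussian blur (sigma 1.1), local maxima above a pixel threshold, and
  sub-pixel 2D Gaussian fits: `detect_spots()`.
- **Colocalization** — one-to-one nearest matching within a radius (1 px for
  modification calling, 2 px for antibody validation), detection-rate /
  sensitivity / specificity metrics: `match_spots()`, `detection_metrics()`.
- **Round alignment** — phase cross-correlation on fiducial beads:
  `align_rounds()`.
- **Nanowell registration** — cell occupancy matrix (COM, 121 x 381) from the
  scan, RNA density matrix (RDM, 31 x 51) from the FOVs, exhaustive Pearson
  cross-correlation to place the RDM in the COM, singlet linking:
  `build_com()`, `build_rdm()`, `register_rdm_to_com()`,
  `link_single_cells()`.
- **Quantification** — single-cell and per-gene m6A levels with reliability
  filters (total >= 10 or log-mean expression >= 0.02), one-gene-per-round
  seqFISH decoding, normalization (per-cell totals, log2, gene centering),
  housekeeping QC, t-SNE embedding (perplexity 10): `cell_m6a_level()`,
  `gene_m6a_level()`, `decode_seqfish()`, `normalize_expression()`,
  `qc_cells()`, `embed_cells()`.
- **Probe design** — 25-30 nt candidates at 45-70% GC, homopolymer runs < 5,
  >= 2 nt spacing, 17-nt cross-hybridization filter, 32-probe trim toward
  55% GC, 14-nt readout homology screen, `target + TA + revcomp(readout)`
  assembly: `design_probes()`.
- **Simulator** — in-vitro transcripts with fractional m6ATP incorporation,
  camera-noise FOV rendering, nanowell scans, beads, seqFISH rounds:
  `simulate_ivt()`, `render_fov()`, `simulate_experiment()`.

The key statistic throughout is a binomial fraction: for a cell with `N`
captured molecules of which `k` colocalize with the antibody channel, the
m6A level is `k / N`; per gene, the same ratio is reported only where the
count or expression filter marks it reliable.

## Worked example

```r
library(m6Ascope)

# the 197-nt T7 control template: expected m6A sites per transcript at 50% m6ATP
expected_modified_count(ivt_control_template(), m6atp_fraction = 0.5)
#> [1] 12

# bulk modified-read fraction: 0.14 M m6A+ of 0.51 M total reads
round(100 * cell_m6a_level(0.51e6, 0.14e6))
#> [1] 27

# simulate a small two-phenotype experiment and run the whole pipeline
cfg <- sim_config(com_shape = c(20, 30), rdm_shape = c(6, 9), well_pitch = 8,
                  loading_rate = 0.4, mean_molecules = 220, seqfish_rounds = 0)
sim <- simulate_experiment(cfg, seed = 3)
gates <- tibble::tibble(phenotype = c("K562", "YAC1"), channel = "ch1",
                        min = c(400, 0), max = c(Inf, 399))
res <- run_pipeline(sim, config = list(com_shape = c(20, 30), rdm_shape = c(6, 9),
                                       well_pitch = 8, threshold = 180,
                                       phenotype_gates = gates))
res$registration
#> RDM-to-COM registration: offset (2, 3), r = 0.9717, z = 6.48 [valid]

dplyr::summarise(dplyr::group_by(res$linked, phenotype),
                 m6a_level = sum(m6a_count) / sum(total_count), n = dplyr::n())
#> # A tibble: 2 × 3
#>   phenotype m6a_level     n
#>   <chr>         <dbl> <int>
#> 1 K562          0.285    10
#> 2 YAC1          0.142    11
```

The registration line says the 6 x 9 block of imaged wells sits at offset
(2, 3) in the occupancy grid with a Pearson correlation of 0.97, an outlier
of the correlation map (z = 6.5), so linking is trusted. The final table is
the point of the assay: the two phenotypes were simulated with true m6A
fractions 0.30 and 0.15, and the recovered per-phenotype levels (0.285 and
0.142, from 21 linked singlet cells) reproduce both the ordering and the
~2-fold difference.

A thin CLI over the same functions ships in `inst/scripts/m6ascope`
(subcommands `simulate`, `detect`, `register`, `design-probes`, `run-all`).

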