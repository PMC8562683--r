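#' Default simulated-experiment configuration
#'
#' Encodes the study conditions the simulator emulates: a 121 x 381 nanowell
#' occupancy grid scanned at low magnification, a 31 x 51 field-of-view (FOV)
#' window of the flow cell imaged at high magnification, dilute Poisson cell
#' loading so most occupied wells hold a single cell, two dye-separable
#' phenotypes with distinct m6A fractions, a 9-gene seqFISH panel including
#' three housekeeping genes, and fiducial beads persistent across rounds.
#'
#' @param com_shape nanowell grid `c(rows, cols)`.
#' @param rdm_shape imaged FOV grid `c(rows, cols)`; strictly smaller than
#'   `com_shape`.
#' @param rdm_offset 0-based `c(row, col)` placement of the FOV window on the
#'   well grid; `NULL` draws it uniformly at simulation time.
#' @param well_pitch nanowell edge in scan pixels.
#' @param loading_rate Poisson mean cells/well (0.3: dilute loading).
#' @param phenotypes tibble with `name`, `prob`, `ch1`, `ch2` (mean stain
#'   intensities), `m6a_fraction`.
#' @param genes gene panel (first entries should include the housekeeping
#'   genes used for QC).
#' @param expression_profiles named list: per-phenotype multinomial gene
#'   weights (length = number of genes).
#' @param mean_molecules mean captured polyA+ molecules per cell.
#' @param fov_shape FOV image size in pixels.
#' @param fov_margin blank frame width in pixels around each FOV's signal
#'   region (the wall footprint between wells).
#' @param psf_sigma PSF width in pixels.
#' @param amplitude_meanlog,amplitude_sdlog log-normal spot amplitude
#'   parameters.
#' @param n_beads fiducial beads per FOV.
#' @param bead_drift_max maximum per-round bead drift in pixels.
#' @param min_spot_sep minimum separation enforced between planted molecule
#'   centers in a FOV.
#' @param noise a [noise_model()].
#' @param seqfish_rounds number of hybridization rounds (one gene per round);
#'   0 disables seqFISH simulation.
#' @return A `sim_config` list.
#' @export
sim_config <- function(com_shape = c(121, 381),
                       rdm_shape = c(31, 51),
                       rdm_offset = NULL,
                       well_pitch = 10,
                       loading_rate = 0.3,
                       phenotypes = tibble::tibble(
                         name = c("K562", "YAC1"),
                         prob = c(0.5, 0.5),
                         ch1 = c(900, 120),
                         ch2 = c(120, 900),
                         m6a_fraction = c(0.30, 0.15)
                       ),
                       genes = c("GAPDH", "ENO1", "EEF2", "HBG1", "BCL2A1",
                                 "MYC", "CD34", "CD14", "TFRC"),
                       expression_profiles = NULL,
                       mean_molecules = 250,
                       fov_shape = c(128, 128),
                       fov_margin = 6,
                       psf_sigma = 1.3,
                       amplitude_meanlog = log(800),
                       amplitude_sdlog = 0.25,
                       n_beads = 6,
                       bead_drift_max = 2,
                       min_spot_sep = 5,
                       noise = noise_model(background_level = 100,
                                           photon_gain = 1,
                                           read_noise_sd = 2),
                       seqfish_rounds = length(genes)) {
  if (is.null(expression_profiles)) {
    # distinct per-phenotype profiles; housekeeping genes expressed in both
    g <- length(genes)
    base <- rep(1, g)
    p1 <- base; p2 <- base
    if (g >= 4) p1[seq(4, g, by = 2)] <- 4
    if (g >= 5) p2[seq(5, g, by = 2)] <- 4
    expression_profiles <- stats::setNames(
      list(p1 / sum(p1), p2 / sum(p2))[seq_len(nrow(phenotypes))],
      phenotypes$name)
  }
  cfg <- list(com_shape = com_shape, rdm_shape = rdm_shape,
              rdm_offset = rdm_offset, well_pitch = well_pitch,
              loading_rate = loading_rate, phenotypes = phenotypes,
              genes = genes, expression_profiles = expression_profiles,
              mean_molecules = mean_molecules, fov_shape = fov_shape,
              fov_margin = fov_margin, psf_sigma = psf_sigma,
              amplitude_meanlog = amplitude_meanlog,
              amplitude_sdlog = amplitude_sdlog, n_beads = n_beads,
              bead_drift_max = bead_drift_max, min_spot_sep = min_spot_sep,
              noise = noise, seqfish_rounds = seqfish_rounds)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  errs <- character()
  if (any(cfg$com_shape <= 0) || any(cfg$rdm_shape <= 0)) {
    errs <- c(errs, "grid shapes must be positive")
  }
  if (cfg$rdm_shape[1] >= cfg$com_shape[1] ||
      cfg$rdm_shape[2] >= cfg$com_shape[2]) {
    errs <- c(errs, "RDM grid must be strictly smaller than the COM grid")
  }
  if (cfg$well_pitch < 4) {
    errs <- c(errs, "well pitch too small to separate wells (need >= 4 px)")
  }
  if (abs(sum(cfg$phenotypes$prob) - 1) > 1e-9) {
    errs <- c(errs, "phenotype probabilities must sum to 1")
  }
  if (any(cfg$phenotypes$m6a_fraction < 0 | cfg$phenotypes$m6a_fraction > 1)) {
    errs <- c(errs, "m6a fractions must lie in [0, 1]")
  }
  if (!all(names(cfg$expression_profiles) %in% cfg$phenotypes$name)) {
    errs <- c(errs, "expression profiles name unknown phenotypes")
  }
  for (p in names(cfg$expression_profiles)) {
    if (length(cfg$expression_profiles[[p]]) != length(cfg$genes)) {
      errs <- c(errs, sprintf(
        "expression profile for '%s' has %d weights but the panel has %d genes",
        p, length(cfg$expression_profiles[[p]]), length(cfg$genes)))
    }
  }
  if (cfg$seqfish_rounds > length(cfg$genes)) {
    errs <- c(errs, "more seqFISH rounds than genes in the panel")
  }
  if (2 * cfg$fov_margin >= min(cfg$fov_shape)) {
    errs <- c(errs, "FOV margin leaves no signal region")
  }
  if (length(errs)) {
    stop(paste0("invalid simulation config:\n  - ",
                paste(errs, collapse = "\n  - ")), call. = FALSE)
  }
  cfg
}

#' Render a nanowell scan from per-well cell records
#'
#' One fluorescent blob per cell at its well position (with sub-well jitter),
#' rendered in a nuclear channel plus one channel per stain; per-channel blob
#' intensity encodes the phenotype. Returns the multi-channel image and the
#' pixel-to-well geometry.
#'
#' @param well_cells tibble with `well_row`, `well_col` (1-based),
#'   `phenotype`, `ch1`, `ch2` intensity columns (one row per cell).
#' @param grid well grid `c(rows, cols)`.
#' @param well_pitch well edge in pixels (>= 4).
#' @param blob_sigma blob width in pixels; default `well_pitch / 6`.
#' @param noise a [noise_model()].
#' @param seed integer seed.
#' @return List: `images` (named list nuclear/ch1/ch2 matrices),
#'   `well_pitch`, `grid`, `cells` (the input with pixel positions added).
#' @export
simulate_nanowell_scan <- function(well_cells, grid = c(121, 381),
                                   well_pitch = 10, blob_sigma = NULL,
                                   noise = noise_model(background_level = 20,
                                                       read_noise_sd = 1),
                                   seed = NULL) {
  if (well_pitch < 4) {
    stop("well pitch too small to separate wells (need >= 4 px)", call. = FALSE)
  }
  if (nrow(well_cells) > 0 &&
      (any(well_cells$well_row > grid[1]) || any(well_cells$well_col > grid[2]))) {
    stop("well grid does not fit all cells", call. = FALSE)
  }
  blob_sigma <- blob_sigma %||% (well_pitch / 6)
  shape <- grid * well_pitch
  with_seed(seed, {
    cells <- well_cells
    if (nrow(cells) > 0) {
      jit <- well_pitch / 8
      cells$row <- (cells$well_row - 1) * well_pitch + (well_pitch - 1) / 2 +
        stats::runif(nrow(cells), -jit, jit)
      cells$col <- (cells$well_col - 1) * well_pitch + (well_pitch - 1) / 2 +
        stats::runif(nrow(cells), -jit, jit)
    } else {
      cells$row <- numeric(); cells$col <- numeric()
    }
    mk <- function(amplitude) {
      sp <- tibble::tibble(row = cells$row, col = cells$col,
                           amplitude = amplitude, channel = "x")
      render_fov(sp, shape = shape, psf_sigma = blob_sigma, noise = noise,
                 channels = "x")$x
    }
    images <- list(
      nuclear = mk(if (nrow(cells)) rep(1000, nrow(cells)) else numeric()),
      ch1 = mk(cells$ch1),
      ch2 = mk(cells$ch2)
    )
    list(images = images, well_pitch = well_pitch, grid = grid, cells = cells)
  })
}

# Draw n spot centers in the FOV signal region with a minimum separation
# (rejection sampling with a bounded retry budget).
draw_centers <- function(n, fov_shape, margin, min_sep) {
  lo_r <- margin; hi_r <- fov_shape[1] - 1 - margin
  lo_c <- margin; hi_c <- fov_shape[2] - 1 - margin
  rows <- numeric(0); cols <- numeric(0)
  tries <- 0L
  while (length(rows) < n && tries < 60L * n + 200L) {
    tries <- tries + 1L
    r <- stats::runif(1, lo_r, hi_r); c <- stats::runif(1, lo_c, hi_c)
    if (length(rows) == 0 ||
        all((rows - r)^2 + (cols - c)^2 > min_sep^2)) {
      rows <- c(rows, r); cols <- c(cols, c)
    }
  }
  n_got <- length(rows)
  cbind(rows, cols)[seq_len(n_got), , drop = FALSE]
}

#' Simulate a full single-cell m6A imaging experiment
#'
#' End-to-end forward model of the workflow: cells are loaded into nanowells
#' (Poisson), phenotyped, and scanned at low magnification; each cell's
#' captured polyA+ molecules are planted as diffraction-limited spots in the
#' high-magnification FOV of its well, arranged as a dense square of signal
#' inside a blank frame (the well wall footprint); each molecule carries an
#' m6A label with its cell's phenotype-specific probability and modified
#' molecules appear (with sub-pixel jitter) in the modification channel;
#' fiducial beads appear in a dedicated channel in every round, displaced by
#' recorded per-round drifts; and, when enabled, each molecule's gene places
#' it in exactly one seqFISH round.
#'
#' Only the wells under the imaged FOV window (the RDM footprint placed at
#' `rdm_offset`) get rendered images. The ground truth records everything
#' planted, so every downstream stage is checkable.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; the simulation is bit-identical per seed.
#' @param render_images render FOV images (set `FALSE` for matrix-level
#'   tests that only need ground truth and the scan).
#' @return A `sim_experiment` list: `ground_truth` (list of `wells`, `spots`,
#'   `beads`, `bead_drift`, `rdm_offset`, `seed`), `scan` (nanowell scan),
#'   `fovs` (list of per-FOV image lists: `total`, `m6a`, `beads`, and
#'   `rounds` when seqFISH is on), `config`.
#' @export
simulate_experiment <- function(config = sim_config(), seed = 1,
                                render_images = TRUE) {
  cfg <- validate_sim_config(config)
  with_seed(seed, {
    nr <- cfg$com_shape[1]; nc <- cfg$com_shape[2]
    # --- load cells into wells ---
    n_cells_per_well <- stats::rpois(nr * nc, cfg$loading_rate)
    well_idx <- which(n_cells_per_well > 0)
    cells <- dplyr::bind_rows(
      list(tibble::tibble(well_row = integer(), well_col = integer(),
                          phenotype = character())),
      lapply(well_idx, function(w) {
        k <- n_cells_per_well[w]
        ph <- sample(cfg$phenotypes$name, k, replace = TRUE,
                     prob = cfg$phenotypes$prob)
        tibble::tibble(
          well_row = (w - 1) %% nr + 1L,
          well_col = (w - 1) %/% nr + 1L,
          phenotype = ph
        )
      }))
    if (nrow(cells) > 0) {
      pi_ <- match(cells$phenotype, cfg$phenotypes$name)
      cells$ch1 <- cfg$phenotypes$ch1[pi_] * stats::runif(nrow(cells), 0.8, 1.2)
      cells$ch2 <- cfg$phenotypes$ch2[pi_] * stats::runif(nrow(cells), 0.8, 1.2)
    } else {
      cells$ch1 <- numeric(); cells$ch2 <- numeric()
    }
    # --- placement of the imaged window ---
    off <- cfg$rdm_offset %||% c(
      sample.int(nr - cfg$rdm_shape[1] + 1, 1) - 1L,
      sample.int(nc - cfg$rdm_shape[2] + 1, 1) - 1L
    )
    # --- per-cell molecule counts, modification, gene identity ---
    if (nrow(cells) > 0) {
      cells$n_molecules <- stats::rpois(nrow(cells), cfg$mean_molecules)
      frac <- cfg$phenotypes$m6a_fraction[match(cells$phenotype,
                                                cfg$phenotypes$name)]
      cells$n_m6a <- stats::rbinom(nrow(cells), cells$n_molecules, frac)
    } else {
      cells$n_molecules <- integer(); cells$n_m6a <- integer()
    }
    # per-well aggregation
    wells <- dplyr::summarise(
      dplyr::group_by(cells, .data$well_row, .data$well_col),
      n_cells = dplyr::n(),
      phenotype = if (dplyr::n() == 1) .data$phenotype[1] else NA_character_,
      total_molecules = sum(.data$n_molecules),
      m6a_molecules = sum(.data$n_m6a),
      .groups = "drop"
    )
    # --- plant spots for wells inside the imaged window ---
    in_window <- function(wr, wc) {
      wr > off[1] & wr <= off[1] + cfg$rdm_shape[1] &
        wc > off[2] & wc <= off[2] + cfg$rdm_shape[2]
    }
    spot_rows <- list()
    gene_count_rows <- list()
    if (nrow(wells) > 0) {
      ww <- wells[in_window(wells$well_row, wells$well_col), ]
      for (i in seq_len(nrow(ww))) {
        wr <- ww$well_row[i]; wc <- ww$well_col[i]
        sub <- cells[cells$well_row == wr & cells$well_col == wc, ]
        n_tot <- sum(sub$n_molecules)
        if (n_tot == 0) next
        centers <- draw_centers(n_tot, cfg$fov_shape, cfg$fov_margin,
                                cfg$min_spot_sep)
        n_placed <- nrow(centers)
        # molecule-level labels drawn per cell, concatenated, then truncated
        # to the number of placeable centers
        labs <- dplyr::bind_rows(lapply(seq_len(nrow(sub)), function(k) {
          nm <- sub$n_molecules[k]
          mod <- c(rep(TRUE, sub$n_m6a[k]), rep(FALSE, nm - sub$n_m6a[k]))
          prof <- cfg$expression_profiles[[sub$phenotype[k]]]
          tibble::tibble(
            modified = sample(mod),
            gene = sample(cfg$genes, nm, replace = TRUE, prob = prof)
          )
        }))
        labs <- labs[seq_len(n_placed), , drop = FALSE]
        amp <- stats::rlnorm(n_placed, cfg$amplitude_meanlog,
                             cfg$amplitude_sdlog)
        spot_rows[[length(spot_rows) + 1]] <- tibble::tibble(
          well_row = wr, well_col = wc,
          fov_row = wr - off[1], fov_col = wc - off[2],
          row = centers[, 1], col = centers[, 2],
          amplitude = amp,
          modified = labs$modified, gene = labs$gene
        )
      }
    }
    spots <- if (length(spot_rows)) dplyr::bind_rows(spot_rows) else
      tibble::tibble(well_row = integer(), well_col = integer(),
                     fov_row = integer(), fov_col = integer(),
                     row = numeric(), col = numeric(), amplitude = numeric(),
                     modified = logical(), gene = character())
    # reconcile planted truth with what was actually placeable
    placed <- dplyr::summarise(
      dplyr::group_by(spots, .data$well_row, .data$well_col),
      total_molecules = dplyr::n(),
      m6a_molecules = sum(.data$modified), .groups = "drop")
    wells <- dplyr::rows_update(
      wells, placed, by = c("well_row", "well_col"), unmatched = "ignore")
    # --- beads, persistent across rounds with per-round drift ---
    n_rounds <- 1L + max(0L, cfg$seqfish_rounds)  # round 1 = m6A detection
    bead_drift <- tibble::tibble(
      round = seq_len(n_rounds),
      drow = c(0, stats::runif(n_rounds - 1, -cfg$bead_drift_max,
                               cfg$bead_drift_max)),
      dcol = c(0, stats::runif(n_rounds - 1, -cfg$bead_drift_max,
                               cfg$bead_drift_max))
    )
    beads <- dplyr::bind_rows(lapply(seq_len(cfg$rdm_shape[1]), function(i) {
      dplyr::bind_rows(lapply(seq_len(cfg$rdm_shape[2]), function(j) {
        ctr <- draw_centers(cfg$n_beads, cfg$fov_shape,
                            cfg$fov_margin + cfg$bead_drift_max + 1, 8)
        tibble::tibble(fov_row = i, fov_col = j,
                       row = ctr[, 1], col = ctr[, 2])
      }))
    }))
    bead_amp <- 10 * exp(cfg$amplitude_meanlog)
    round_gene_map <- if (cfg$seqfish_rounds > 0) {
      tibble::tibble(round = seq_len(cfg$seqfish_rounds),
                     gene = cfg$genes[seq_len(cfg$seqfish_rounds)])
    } else NULL
    # --- render ---
    fovs <- NULL
    if (render_images) {
      fovs <- vector("list", cfg$rdm_shape[1] * cfg$rdm_shape[2])
      dim(fovs) <- cfg$rdm_shape
      for (i in seq_len(cfg$rdm_shape[1])) for (j in seq_len(cfg$rdm_shape[2])) {
        sp <- spots[spots$fov_row == i & spots$fov_col == j, ]
        bd <- beads[beads$fov_row == i & beads$fov_col == j, ]
        mk_bead <- function(drift) tibble::tibble(
          row = bd$row + drift[1], col = bd$col + drift[2],
          amplitude = bead_amp, channel = "beads")
        total_sp <- tibble::tibble(row = sp$row, col = sp$col,
                                   amplitude = sp$amplitude, channel = "total")
        m6a_sp <- {
          m <- sp[sp$modified, ]
          tibble::tibble(
            row = m$row + stats::rnorm(nrow(m), 0, 0.05),
            col = m$col + stats::rnorm(nrow(m), 0, 0.05),
            amplitude = if (nrow(m)) stats::rlnorm(nrow(m),
                                                   cfg$amplitude_meanlog,
                                                   cfg$amplitude_sdlog)
            else numeric(),
            channel = "m6a")
        }
        d1 <- c(bead_drift$drow[1], bead_drift$dcol[1])
        imgs <- render_fov(dplyr::bind_rows(total_sp, m6a_sp, mk_bead(d1)),
                           shape = cfg$fov_shape, psf_sigma = cfg$psf_sigma,
                           noise = cfg$noise,
                           channels = c("total", "m6a", "beads"))
        fov <- list(total = imgs$total, m6a = imgs$m6a, beads = imgs$beads)
        if (cfg$seqfish_rounds > 0) {
          fov$rounds <- lapply(seq_len(cfg$seqfish_rounds), function(r) {
            g <- round_gene_map$gene[r]
            gsp <- sp[sp$gene == g, ]
            drift <- c(bead_drift$drow[r + 1], bead_drift$dcol[r + 1])
            rimgs <- render_fov(
              dplyr::bind_rows(
                tibble::tibble(row = gsp$row + drift[1],
                               col = gsp$col + drift[2],
                               amplitude = if (nrow(gsp))
                                 stats::rlnorm(nrow(gsp),
                                               cfg$amplitude_meanlog,
                                               cfg$amplitude_sdlog)
                               else numeric(),
                               channel = "gene"),
                mk_bead(drift)),
              shape = cfg$fov_shape, psf_sigma = cfg$psf_sigma,
              noise = cfg$noise, channels = c("gene", "beads"))
            rimgs
          })
        }
        fovs[[i, j]] <- fov
      }
    }
    scan <- simulate_nanowell_scan(cells, grid = cfg$com_shape,
                                   well_pitch = cfg$well_pitch)
    gene_counts <- if (nrow(spots)) {
      dplyr::count(spots, .data$well_row, .data$well_col, .data$gene,
                   name = "count")
    } else {
      tibble::tibble(well_row = integer(), well_col = integer(),
                     gene = character(), count = integer())
    }
    structure(list(
      ground_truth = list(wells = wells, cells = cells, spots = spots,
                          gene_counts = gene_counts,
                          beads = beads, bead_drift = bead_drift,
                          rdm_offset = off, round_gene_map = round_gene_map,
                          seed = seed),
      scan = scan,
      fovs = fovs,
      config = cfg
    ), class = "sim_experiment")
  })
}

#' Ground-truth occupancy matrix of a simulated experiment
#' @param sim a `sim_experiment`.
#' @return Integer matrix of planted per-well cell counts.
#' @export
true_com <- function(sim) {
  build_com(sim$ground_truth$cells, shape = sim$config$com_shape)
}
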