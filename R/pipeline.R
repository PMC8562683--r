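#' Validate and default a pipeline configuration
#'
#' Fills unset keys with the pipeline's standard parameters — rolling-ball
#' radius 3 px, blur sigma 1.1, colocalization radius 1 px (2 px in antibody
#' validation mode), t-SNE perplexity 10, COM 121 x 381, RDM 31 x 51,
#' registration outlier z-threshold 5 — and checks every invariant, reporting
#' all violations together.
#'
#' @param config named list of overrides (may be empty).
#' @return A validated `pipeline_config` list.
#' @export
validate_config <- function(config = list()) {
  defaults <- list(
    com_shape = c(121, 381),
    rdm_shape = c(31, 51),
    well_pitch = 10,
    rolling_ball_radius = 3,
    blur_sigma = 1.1,
    threshold = NULL,          # estimated per image when NULL
    threshold_k = 5,
    min_spot_sep = 2,
    fit_window = 3L,
    match_dist = 1,            # px, modification calling
    validation_match_dist = 2, # px, antibody validation mode
    alignment_quality_floor = 0.05,
    registration_z = 5,
    perplexity = 10,
    min_detect_housekeeping = 1,
    housekeeping = c("GAPDH", "ENO1", "EEF2"),
    round_gene_map = NULL,
    gene_panel = NULL,
    phenotype_gates = NULL,
    seed = 1
  )
  unknown <- setdiff(names(config), names(defaults))
  cfg <- utils::modifyList(defaults, config[setdiff(names(config), unknown)],
                           keep.null = TRUE)
  errs <- character()
  if (length(unknown)) {
    errs <- c(errs, sprintf("unknown config key(s): %s",
                            paste(unknown, collapse = ", ")))
  }
  if (any(cfg$com_shape <= 0) || any(cfg$rdm_shape <= 0)) {
    errs <- c(errs, "grid shapes must be positive")
  } else if (cfg$rdm_shape[1] >= cfg$com_shape[1] ||
             cfg$rdm_shape[2] >= cfg$com_shape[2]) {
    errs <- c(errs, "RDM shape must be strictly smaller than COM shape")
  }
  for (key in c("rolling_ball_radius", "blur_sigma", "match_dist",
                "validation_match_dist", "well_pitch")) {
    if (cfg[[key]] <= 0) errs <- c(errs, sprintf("%s must be > 0", key))
  }
  if (!is.null(cfg$threshold) && cfg$threshold < 0) {
    errs <- c(errs, "threshold must be >= 0")
  }
  if (cfg$perplexity <= 0) errs <- c(errs, "perplexity must be > 0")
  if (!is.null(cfg$round_gene_map)) {
    if (!all(c("round", "gene") %in% names(cfg$round_gene_map))) {
      errs <- c(errs, "round_gene_map needs columns round, gene")
    } else if (!is.null(cfg$gene_panel) &&
               !all(cfg$round_gene_map$gene %in% cfg$gene_panel)) {
      errs <- c(errs, sprintf(
        "round_gene_map names gene(s) absent from the panel: %s",
        paste(setdiff(cfg$round_gene_map$gene, cfg$gene_panel),
              collapse = ", ")))
    }
  }
  if (length(errs)) {
    stop(paste0("invalid configuration:\n  - ",
                paste(errs, collapse = "\n  - ")), call. = FALSE)
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis pipeline on a simulated (or loaded) experiment
#'
#' Orchestrates the stages in acquisition order: cell detection and
#' phenotyping on the nanowell scan, occupancy-matrix construction, per-FOV
#' spot detection in the total and modification channels, bead-based round
#' alignment, colocalization calling, RNA-density-matrix construction,
#' RDM-to-COM registration, singlet linking, and — when seqFISH rounds are
#' present — round decoding, normalization, QC and embedding. Any stage
#' failure aborts with the stage name; partial results accumulated so far are
#' attached to the error condition.
#'
#' @param experiment a `sim_experiment` from [simulate_experiment()] (with
#'   rendered images), or a bundle of the same shape loaded from disk.
#' @param config a [validate_config()] list or raw override list.
#' @param out_dir optional directory; when given, every intermediate table is
#'   written as CSV together with a JSON run manifest.
#' @param embed run the t-SNE embedding when enough cells pass QC.
#' @return A `pipeline_result` list: `cells`, `com`, `fov_counts`, `rdm`,
#'   `registration`, `linked`, and (seqFISH) `expression`, `qc`, `normalized`,
#'   `embedding`, plus `config`.
#' @export
run_pipeline <- function(experiment, config = list(), out_dir = NULL,
                         embed = FALSE) {
  cfg <- if (inherits(config, "pipeline_config")) config else
    validate_config(config)
  if (is.null(experiment$fovs)) {
    stop("stage detect_spots: experiment has no rendered FOV images",
         call. = FALSE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage %s: %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  scan <- experiment$scan
  cells <- stage("detect_cells", detect_cells(scan$images, scan$well_pitch))
  if (!is.null(cfg$phenotype_gates)) {
    cells <- stage("classify_phenotype",
                   classify_phenotype(cells, cfg$phenotype_gates))
  } else {
    cells$phenotype <- NA_character_
  }
  com_shape <- experiment$config$com_shape %||% cfg$com_shape
  rdm_shape <- experiment$config$rdm_shape %||% cfg$rdm_shape
  com <- stage("build_com", build_com(cells, shape = com_shape))
  # --- per-FOV detection and colocalization ---
  fov_counts <- list(); round_spots <- list(); m6a_maps <- list()
  rounds_present <- !is.null(experiment$fovs[[1, 1]]$rounds)
  for (i in seq_len(rdm_shape[1])) for (j in seq_len(rdm_shape[2])) {
    fov <- experiment$fovs[[i, j]]
    if (is.null(fov)) next
    total <- stage("detect_spots", detect_spots(
      fov$total, threshold = cfg$threshold,
      radius = cfg$rolling_ball_radius, sigma = cfg$blur_sigma,
      min_sep = cfg$min_spot_sep, window = cfg$fit_window,
      threshold_k = cfg$threshold_k))
    m6a <- stage("detect_spots", detect_spots(
      fov$m6a, threshold = cfg$threshold,
      radius = cfg$rolling_ball_radius, sigma = cfg$blur_sigma,
      min_sep = cfg$min_spot_sep, window = cfg$fit_window,
      threshold_k = cfg$threshold_k))
    total <- total[total$status == "ok", ]
    m6a <- m6a[m6a$status == "ok", ]
    m <- stage("match_spots", match_spots(total, m6a,
                                          max_dist = cfg$match_dist))
    fov_counts[[length(fov_counts) + 1]] <- tibble::tibble(
      fov_row = i, fov_col = j,
      total_count = nrow(total), m6a_count = nrow(m$pairs))
    m6a_maps[[length(m6a_maps) + 1]] <- {
      mt <- total[m$pairs$idx_a, c("row", "col")]
      mt$fov_row <- i; mt$fov_col <- j
      mt
    }
    if (rounds_present) {
      ref_beads <- fov$beads
      for (r in seq_along(fov$rounds)) {
        rimg <- fov$rounds[[r]]
        offs <- stage("align_rounds",
                      align_rounds(rimg$beads, ref_beads,
                                   quality_floor = cfg$alignment_quality_floor,
                                   round = r))
        gsp <- stage("detect_spots", detect_spots(
          rimg$gene, threshold = cfg$threshold,
          radius = cfg$rolling_ball_radius, sigma = cfg$blur_sigma,
          min_sep = cfg$min_spot_sep, window = cfg$fit_window,
          threshold_k = cfg$threshold_k))
        gsp <- apply_offset(gsp[gsp$status == "ok", ], offs)
        if (nrow(gsp)) {
          gsp$fov_row <- i; gsp$fov_col <- j; gsp$round <- r
          round_spots[[length(round_spots) + 1]] <-
            gsp[, c("fov_row", "fov_col", "round", "row", "col")]
        }
      }
    }
  }
  fov_counts <- dplyr::bind_rows(fov_counts)
  rdm <- stage("build_rdm", build_rdm(fov_counts, shape = rdm_shape))
  reg <- stage("register_rdm_to_com",
               register_rdm_to_com(rdm, com, z_threshold = cfg$registration_z))
  linked <- stage("link_single_cells", link_single_cells(reg, com, cells, rdm))
  result <- list(cells = cells, com = com, fov_counts = fov_counts,
                 rdm = rdm, registration = reg, linked = linked,
                 config = cfg)
  if (rounds_present && nrow(linked) > 0) {
    rgm <- cfg$round_gene_map %||% experiment$ground_truth$round_gene_map
    cell_info <- linked
    cell_info$cell_id <- sprintf("cell_%d_%d", cell_info$well_row,
                                 cell_info$well_col)
    cell_info$fov_row <- cell_info$rdm_row
    cell_info$fov_col <- cell_info$rdm_col
    m6a_map <- dplyr::bind_rows(m6a_maps)
    expr <- stage("decode_seqfish", decode_seqfish(
      dplyr::bind_rows(round_spots), rgm, cell_info,
      m6a_spots = m6a_map, m6a_match_dist = cfg$match_dist))
    result$expression <- expr
    hk <- intersect(cfg$housekeeping, rownames(expr$counts))
    if (length(hk)) {
      result$qc <- stage("qc_cells", qc_cells(
        expr, housekeeping = hk, min_detect = cfg$min_detect_housekeeping))
    }
    result$normalized <- stage("normalize_expression",
                               normalize_expression(expr))
    if (embed &&
        ncol(result$normalized$values) > 3 * cfg$perplexity + 1) {
      result$embedding <- stage("embed_cells", embed_cells(
        result$normalized, perplexity = cfg$perplexity, seed = cfg$seed))
    }
  }
  class(result) <- "pipeline_result"
  if (!is.null(out_dir)) write_pipeline_result(result, out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    "pipeline result: %d cells detected, %d linked singlets, registration %s\n",
    nrow(x$cells), nrow(x$linked),
    if (x$registration$valid) "valid" else "INVALID"))
  invisible(x)
}
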