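#' Read / write images and result tables
#'
#' Images move as multi-page TIFF (one page per channel, float32); tabular
#' results (spots, matched pairs, matrices, linked cells, expression) as CSV;
#' every pipeline run can be dumped with a JSON manifest recording the
#' configuration and seed so any run is reproducible from its output folder.
#'
#' @name m6ascope_io
NULL

#' Write a named list of channel matrices as a multi-page TIFF
#' @param images named list of numeric matrices.
#' @param path output path.
#' @param scale intensities are divided by `scale` before writing (TIFF
#'   float pages round-trip exactly; pick 1 to keep raw counts).
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(images, path, scale = 1) {
  stopifnot(is.list(images))
  tiff::writeTIFF(lapply(images, function(m) m / scale), path,
                  bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' Read a multi-page TIFF as a list of matrices
#' @param path TIFF path.
#' @param channels optional channel names for the pages.
#' @param scale multiplier applied after reading.
#' @return Named list of numeric matrices.
#' @export
read_image_tiff <- function(path, channels = NULL, scale = 1) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  out <- lapply(pages, function(p) p * scale)
  if (!is.null(channels)) names(out) <- channels
  out
}

#' Write spots to CSV with round/channel metadata
#' @param spots spot tibble.
#' @param path output path.
#' @param round,channel metadata columns added if absent.
#' @return `path`, invisibly.
#' @export
write_spots_csv <- function(spots, path, round = NA, channel = NA) {
  if (!"round" %in% names(spots)) spots$round <- round
  if (!"channel" %in% names(spots)) spots$channel <- channel
  utils::write.csv(spots, path, row.names = FALSE)
  invisible(path)
}

#' Write a matrix (COM, RDM, expression) to CSV
#' @param m matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(m, path) {
  utils::write.csv(as.data.frame(m), path,
                   row.names = !is.null(rownames(m)))
  invisible(path)
}

#' Dump a pipeline result bundle to a directory
#'
#' Writes every tabular intermediate as CSV, the registration report, and a
#' `manifest.json` with the configuration, seed and package version.
#'
#' @param result a `pipeline_result`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_result <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  utils::write.csv(result$cells, p("cells.csv"), row.names = FALSE)
  write_matrix_csv(result$com, p("com.csv"))
  write_matrix_csv(result$rdm$total, p("rdm_total.csv"))
  write_matrix_csv(result$rdm$modified, p("rdm_m6a.csv"))
  utils::write.csv(result$fov_counts, p("fov_counts.csv"), row.names = FALSE)
  utils::write.csv(glance(result$registration), p("registration.csv"),
                   row.names = FALSE)
  utils::write.csv(result$linked, p("linked_cells.csv"), row.names = FALSE)
  if (!is.null(result$expression)) {
    write_matrix_csv(result$expression$counts, p("expression_counts.csv"))
    write_matrix_csv(result$expression$modified, p("expression_m6a.csv"))
    utils::write.csv(result$expression$cells, p("cell_annotations.csv"),
                     row.names = FALSE)
  }
  if (!is.null(result$embedding)) {
    utils::write.csv(result$embedding, p("embedding.csv"), row.names = FALSE)
  }
  cfg <- result$config
  cfg$round_gene_map <- if (!is.null(cfg$round_gene_map))
    as.list(cfg$round_gene_map) else NULL
  cfg$phenotype_gates <- if (!is.null(cfg$phenotype_gates))
    as.list(cfg$phenotype_gates) else NULL
  manifest <- list(package = "m6Ascope",
                   version = as.character(utils::packageVersion("m6Ascope")),
                   config = unclass(cfg),
                   written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(out_dir)
}

#' Read a FASTA file as a named character vector
#'
#' Thin wrapper over Biostrings for the probe-design inputs.
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("reading FASTA requires the Biostrings package", call. = FALSE)
  }
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}
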