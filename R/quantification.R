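#' Single-cell m6A level
#'
#' The fraction of a cell's captured polyA+ molecules that scored as m6A
#' modified: `modified / total`. Undefined (NA) for cells with no captured
#' molecules.
#'
#' @param total total molecule count(s) per cell.
#' @param modified modified molecule count(s) per cell.
#' @return Numeric vector of fractions in [0, 1]; `NA` where `total` is 0.
#' @examples
#' cell_m6a_level(0.51e6, 0.14e6)  # ~0.27
#' @export
cell_m6a_level <- function(total, modified) {
  stopifnot(length(total) == length(modified))
  if (any(total < 0 | modified < 0)) stop("counts must be >= 0", call. = FALSE)
  if (any(modified > total)) {
    stop("modified count exceeds total count (upstream bug)", call. = FALSE)
  }
  ifelse(total > 0, modified / total, NA_real_)
}

#' Gene-level m6A level with reliability filters
#'
#' The percentage of modified gene-specific transcripts among total
#' gene-specific transcripts, reported only when the estimate is reliable:
#' total gene-specific counts of at least `min_total` (default 10) OR a
#' log-mean gene expression level of at least `min_log_mean_expr` (default
#' 0.02). Otherwise not applicable (NA).
#'
#' @param gene_total gene-specific total transcript count(s).
#' @param gene_modified gene-specific modified count(s).
#' @param log_mean_expr log-mean expression level(s) of the gene.
#' @param min_total count filter threshold.
#' @param min_log_mean_expr expression filter threshold. Pass a negative
#'   value (e.g. -0.02) to reproduce the alternative sign convention used in
#'   some displays.
#' @return Numeric vector of fractions in [0, 1], `NA` where both filters
#'   fail or where `gene_total` is 0.
#' @export
gene_m6a_level <- function(gene_total, gene_modified, log_mean_expr,
                           min_total = 10, min_log_mean_expr = 0.02) {
  if (any(gene_modified > gene_total)) {
    stop("modified count exceeds total count (upstream bug)", call. = FALSE)
  }
  ok <- (gene_total >= min_total) | (log_mean_expr >= min_log_mean_expr)
  out <- ifelse(ok & gene_total > 0, gene_modified / gene_total, NA_real_)
  out
}

#' Decode sequential FISH rounds into an expression matrix
#'
#' In the one-gene-per-round scheme, each hybridization round images exactly
#' one gene's readout probe; the per-(gene, cell) count is therefore the spot
#' count of that gene's round in the cell's FOV. When a pre-hybridization m6A
#' spot map is supplied, each round's spots are colocalized against it
#' (within `m6a_match_dist`) to yield per-(gene, cell) modified counts.
#'
#' @param round_spots tibble of aligned spots across rounds with columns
#'   `fov_row`, `fov_col`, `round`, `row`, `col`.
#' @param round_gene_map tibble with `round`, `gene`: one gene per round.
#' @param cell_info tibble identifying the cells, one row per FOV kept after
#'   linking: columns `cell_id`, `fov_row`, `fov_col` (plus annotations such
#'   as phenotype, total_count, m6a_count, which are carried through).
#' @param m6a_spots optional tibble of m6A-colocalized spot centers with
#'   `fov_row`, `fov_col`, `row`, `col` (the modification map imaged before
#'   the hybridization rounds).
#' @param m6a_match_dist colocalization radius in pixels for coupling rounds
#'   to the modification map (default 1 px).
#' @return An `m6a_expression` object: `counts` (gene x cell matrix),
#'   `modified` (gene x cell matrix, NA when no m6A map given), `cells`
#'   (annotation tibble, one row per cell), `genes`.
#' @export
decode_seqfish <- function(round_spots, round_gene_map, cell_info,
                           m6a_spots = NULL, m6a_match_dist = 1) {
  stopifnot(all(c("round", "gene") %in% names(round_gene_map)))
  if (anyDuplicated(round_gene_map$round)) {
    stop("each round must map to exactly one gene", call. = FALSE)
  }
  if (nrow(round_spots) > 0) {
    unmapped <- setdiff(unique(round_spots$round), round_gene_map$round)
    if (length(unmapped)) {
      stop(sprintf("round(s) with no gene assignment: %s",
                   paste(unmapped, collapse = ", ")), call. = FALSE)
    }
  }
  genes <- round_gene_map$gene
  n_cells <- nrow(cell_info)
  counts <- matrix(0L, length(genes), n_cells,
                   dimnames = list(genes, cell_info$cell_id))
  modified <- matrix(if (is.null(m6a_spots)) NA_integer_ else 0L,
                     length(genes), n_cells,
                     dimnames = dimnames(counts))
  for (k in seq_len(n_cells)) {
    fr <- cell_info$fov_row[k]; fc <- cell_info$fov_col[k]
    fov <- round_spots[round_spots$fov_row == fr & round_spots$fov_col == fc, ]
    mods <- if (!is.null(m6a_spots)) {
      m6a_spots[m6a_spots$fov_row == fr & m6a_spots$fov_col == fc, ]
    } else NULL
    for (g in seq_along(genes)) {
      rnd <- round_gene_map$round[g]
      sp <- fov[fov$round == rnd, ]
      counts[g, k] <- nrow(sp)
      if (!is.null(mods)) {
        m <- match_spots(sp, mods, max_dist = m6a_match_dist)
        modified[g, k] <- nrow(m$pairs)
      }
    }
  }
  structure(list(counts = counts, modified = modified,
                 cells = cell_info, genes = genes),
            class = "m6a_expression")
}

#' @export
print.m6a_expression <- function(x, ...) {
  cat(sprintf("m6A expression matrix: %d genes x %d cells\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' Tidy an expression matrix into long form
#'
#' @param x an `m6a_expression`.
#' @param ... unused.
#' @return Long tibble: `gene`, `cell_id`, `count`, `modified_count`.
#' @export
tidy.m6a_expression <- function(x, ...) {
  tibble::tibble(
    gene = rep(rownames(x$counts), times = ncol(x$counts)),
    cell_id = rep(colnames(x$counts), each = nrow(x$counts)),
    count = as.vector(x$counts),
    modified_count = as.vector(x$modified)
  )
}

#' Normalize an expression matrix
#'
#' Gene counts are divided by each cell's total number of captured RNA
#' molecules, log2-transformed with a pseudocount, and mean-centered per gene
#' across cells:
#' `value = log2(count / total + pseudocount) - mean_over_cells(...)`.
#' Cells with zero total are excluded with a warning.
#'
#' @param expr an `m6a_expression`; cell totals are taken from the
#'   `total_count` annotation when present, else from column sums.
#' @param pseudocount added inside the log; default `1 / total` per cell.
#' @return A `m6a_normalized` object: `values` (gene x cell matrix, each gene
#'   row mean-centered), `log_mean_expr` (per-gene mean of the log2 values
#'   before centering), `cells`.
#' @export
normalize_expression <- function(expr, pseudocount = NULL) {
  stopifnot(inherits(expr, "m6a_expression"))
  totals <- if ("total_count" %in% names(expr$cells)) {
    expr$cells$total_count
  } else {
    colSums(expr$counts)
  }
  keep <- totals > 0
  if (any(!keep)) {
    warning(sprintf("%d cell(s) with zero total excluded from normalization",
                    sum(!keep)), call. = FALSE)
  }
  counts <- expr$counts[, keep, drop = FALSE]
  totals <- totals[keep]
  pc <- if (is.null(pseudocount)) 1 / totals else rep(pseudocount, length(totals))
  lg <- log2(sweep(counts, 2, totals, "/") + matrix(pc, nrow(counts),
                                                    length(pc), byrow = TRUE))
  row_means <- rowMeans(lg)
  structure(list(values = lg - row_means,
                 log_mean_expr = row_means,
                 cells = expr$cells[keep, , drop = FALSE]),
            class = "m6a_normalized")
}

#' t-SNE embedding of normalized single-cell profiles
#'
#' Two-dimensional t-distributed stochastic neighbor embedding of cells,
#' perplexity 10 by default, deterministic per seed.
#'
#' @param norm an `m6a_normalized` object (cells are embedded).
#' @param perplexity t-SNE perplexity; requires more than `3 * perplexity`
#'   cells.
#' @param seed integer seed.
#' @param ... passed to [Rtsne::Rtsne()].
#' @return Tibble with `cell_id`, `tsne1`, `tsne2`, joined with the cell
#'   annotations.
#' @export
embed_cells <- function(norm, perplexity = 10, seed = 1, ...) {
  stopifnot(inherits(norm, "m6a_normalized"))
  x <- t(norm$values)
  n <- nrow(x)
  if (n - 1 < 3 * perplexity) {
    stop(sprintf(
      "too few cells (%d) for perplexity %g; need > 3*perplexity + 1 cells or a lower perplexity",
      n, perplexity), call. = FALSE)
  }
  coords <- with_seed(seed, {
    Rtsne::Rtsne(x, dims = 2, perplexity = perplexity,
                 check_duplicates = FALSE, pca = FALSE, ...)$Y
  })
  out <- tibble::tibble(cell_id = norm$cells$cell_id,
                        tsne1 = coords[, 1], tsne2 = coords[, 2])
  dplyr::left_join(out, norm$cells, by = "cell_id")
}

#' Housekeeping-gene quality control
#'
#' A cell passes QC when at least `min_detect` of the housekeeping genes have
#' nonzero counts.
#'
#' @param expr an `m6a_expression`.
#' @param housekeeping housekeeping gene names (default GAPDH, ENO1, EEF2);
#'   all must be in the panel.
#' @param min_detect minimum number detected to pass (default 1).
#' @return Tibble: `cell_id`, `n_housekeeping_detected`, `qc_pass`.
#' @export
qc_cells <- function(expr, housekeeping = c("GAPDH", "ENO1", "EEF2"),
                     min_detect = 1) {
  stopifnot(inherits(expr, "m6a_expression"))
  miss <- setdiff(housekeeping, rownames(expr$counts))
  if (length(miss)) {
    stop(sprintf("housekeeping gene(s) absent from panel: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  hk <- expr$counts[housekeeping, , drop = FALSE]
  n_det <- unname(colSums(hk > 0))
  tibble::tibble(cell_id = colnames(expr$counts),
                 n_housekeeping_detected = as.integer(n_det),
                 qc_pass = n_det >= min_detect)
}
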