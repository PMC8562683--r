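#' Detect cells in a nanowell scan
#'
#' Find-maxima detection on the nuclear-stain channel of a multicolor
#' low-magnification scan: the channel is lightly smoothed, local maxima
#' above a prominence threshold are taken as cell centers, nearby duplicates
#' are merged, and each channel's intensity is sampled as the mean over a
#' fixed-radius disk around the center. Cells are assigned to wells by the
#' grid geometry.
#'
#' @param scan named list of channel matrices; must contain `nuclear_channel`.
#' @param well_pitch well edge length in pixels (scan rows = grid rows x pitch).
#' @param nuclear_channel name of the nuclear-stain channel.
#' @param threshold prominence threshold on the smoothed nuclear channel;
#'   estimated by [estimate_threshold()] when `NULL`.
#' @param sample_radius disk radius (pixels) for intensity sampling.
#' @param min_sep merge radius for duplicate maxima; default half a pitch
#'   keeps distinct cells within one well separable.
#' @return Tibble of cell records: `row`, `col` (0-based scan pixels), one
#'   intensity column per channel, `well_row`, `well_col` (1-based grid).
#' @export
detect_cells <- function(scan, well_pitch, nuclear_channel = "nuclear",
                         threshold = NULL, sample_radius = 2,
                         min_sep = NULL) {
  if (!nuclear_channel %in% names(scan)) {
    stop(sprintf("nuclear channel '%s' missing from scan", nuclear_channel),
         call. = FALSE)
  }
  nuc <- scan[[nuclear_channel]]
  check_image(nuc, "scan nuclear channel")
  sm <- smooth_gaussian(nuc, sigma = 1)
  if (is.null(threshold)) threshold <- estimate_threshold(sm)
  peaks <- find_local_maxima(sm, threshold)
  min_sep <- min_sep %||% max(2, well_pitch / 3)
  if (nrow(peaks) == 0) {
    out <- tibble::tibble(row = numeric(), col = numeric())
    for (ch in names(scan)) out[[ch]] <- numeric()
    out$well_row <- integer(); out$well_col <- integer()
    return(out)
  }
  peaks <- merge_maxima(peaks, sm[peaks], min_sep = min_sep)
  disk <- ball_element(sample_radius)
  nr <- nrow(nuc); nc <- ncol(nuc)
  sample_disk <- function(img, r, c) {
    rr <- r + disk$dr; cc <- c + disk$dc
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    mean(img[cbind(rr[ok], cc[ok])])
  }
  out <- tibble::tibble(row = peaks[, 1] - 1, col = peaks[, 2] - 1)
  for (ch in names(scan)) {
    out[[ch]] <- vapply(seq_len(nrow(peaks)), function(i) {
      sample_disk(scan[[ch]], peaks[i, 1], peaks[i, 2])
    }, numeric(1))
  }
  out$well_row <- as.integer(floor(out$row / well_pitch)) + 1L
  out$well_col <- as.integer(floor(out$col / well_pitch)) + 1L
  out
}

#' Gate cells into phenotypes by channel intensity
#'
#' Each gate is an axis-aligned rectangle in channel-intensity space (the
#' scatterplot gating used to separate dye-stained cell types). A cell gets
#' the label of the unique gate containing it, or `NA` (unassigned).
#'
#' @param cells cell tibble from [detect_cells()].
#' @param gates tibble with columns `phenotype`, `channel`, `min`, `max`: one
#'   row per (phenotype, channel) bound. Gates must not overlap.
#' @return `cells` with a `phenotype` column added.
#' @export
classify_phenotype <- function(cells, gates) {
  req <- c("phenotype", "channel", "min", "max")
  if (!all(req %in% names(gates))) {
    stop("gates need columns phenotype, channel, min, max", call. = FALSE)
  }
  miss <- setdiff(unique(gates$channel), names(cells))
  if (length(miss)) {
    stop(sprintf("gate channels missing from cells: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  phenos <- unique(gates$phenotype)
  # overlap check: two gates overlap if their intervals intersect on every
  # channel either gate constrains (unconstrained channels span everything)
  if (length(phenos) > 1) {
    chans <- unique(gates$channel)
    bounds <- function(p, ch) {
      g <- gates[gates$phenotype == p & gates$channel == ch, ]
      if (nrow(g) == 0) c(-Inf, Inf) else c(g$min[1], g$max[1])
    }
    for (i in seq_along(phenos)) for (j in seq_along(phenos)) {
      if (i >= j) next
      inter <- vapply(chans, function(ch) {
        a <- bounds(phenos[i], ch); b <- bounds(phenos[j], ch)
        max(a[1], b[1]) < min(a[2], b[2])
      }, logical(1))
      if (all(inter)) {
        stop(sprintf("gates '%s' and '%s' overlap", phenos[i], phenos[j]),
             call. = FALSE)
      }
    }
  }
  inside <- function(i, p) {
    g <- gates[gates$phenotype == p, ]
    all(vapply(seq_len(nrow(g)), function(k) {
      v <- cells[[g$channel[k]]][i]
      v >= g$min[k] & v <= g$max[k]
    }, logical(1)))
  }
  cells$phenotype <- vapply(seq_len(nrow(cells)), function(i) {
    hit <- phenos[vapply(phenos, function(p) inside(i, p), logical(1))]
    if (length(hit) == 1) hit else NA_character_
  }, character(1))
  cells
}

#' Build the cell occupancy matrix (COM)
#'
#' Converts per-cell well assignments into a grid of cell counts per well.
#' Cells falling outside the grid are excluded with a warning.
#'
#' @param cells cell tibble with `well_row`, `well_col` (1-based).
#' @param shape grid dimensions `c(rows, cols)`; default 121 x 381.
#' @return Integer matrix of per-well cell counts.
#' @export
build_com <- function(cells, shape = c(121, 381)) {
  com <- matrix(0L, shape[1], shape[2])
  if (nrow(cells) == 0) return(com)
  ok <- cells$well_row >= 1 & cells$well_row <= shape[1] &
    cells$well_col >= 1 & cells$well_col <= shape[2]
  if (any(!ok)) {
    warning(sprintf("%d cell(s) outside the well grid excluded", sum(!ok)),
            call. = FALSE)
  }
  for (i in which(ok)) {
    com[cells$well_row[i], cells$well_col[i]] <-
      com[cells$well_row[i], cells$well_col[i]] + 1L
  }
  com
}

#' Build the RNA density matrix (RDM)
#'
#' Arranges per-FOV molecule counts (total polyA+ channel and colocalized
#' modification channel) into grid matrices. FOVs absent from `counts` are
#' flagged missing (`NA`) and are excluded from registration.
#'
#' @param counts tibble with `fov_row`, `fov_col` (1-based grid positions),
#'   `total_count`, `m6a_count`.
#' @param shape RDM dimensions `c(rows, cols)`; default 31 x 51.
#' @return An `m6a_rdm` object: list of `total` and `modified` matrices.
#' @export
build_rdm <- function(counts, shape = c(31, 51)) {
  total <- matrix(NA_real_, shape[1], shape[2])
  modified <- matrix(NA_real_, shape[1], shape[2])
  if (nrow(counts) > 0) {
    if (any(counts$m6a_count > counts$total_count)) {
      stop("modified count exceeds total count in some FOV", call. = FALSE)
    }
    ok <- counts$fov_row >= 1 & counts$fov_row <= shape[1] &
      counts$fov_col >= 1 & counts$fov_col <= shape[2]
    if (any(!ok)) {
      warning(sprintf("%d FOV count(s) outside the RDM grid excluded",
                      sum(!ok)), call. = FALSE)
    }
    idx <- cbind(counts$fov_row[ok], counts$fov_col[ok])
    total[idx] <- counts$total_count[ok]
    modified[idx] <- counts$m6a_count[ok]
  }
  structure(list(total = total, modified = modified, shape = shape),
            class = "m6a_rdm")
}
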