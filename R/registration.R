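#' Register the RNA density matrix to the cell occupancy matrix
#'
#' Exhaustive translation search linking the flow-cell molecule counts back
#' to the nanowell grid: the Pearson correlation coefficient is computed
#' between the RDM and every contiguous same-shape subset of the COM, and the
#' offset maximizing it is taken. Registration is declared valid only when
#' the best correlation is an outlier of the correlation map (z-score at
#' least `z_threshold`), since a genuine overlap produces a peak far outside
#' the distribution of chance correlations.
#'
#' Offsets are 0-based: offset `(0, 0)` aligns the RDM with the COM's
#' top-left corner, so RDM entry `(i, j)` maps to COM well
#' `(i + drow, j + dcol)` (1-based matrix indices plus the 0-based offset).
#'
#' Missing RDM entries (`NA`) are excluded pairwise from each correlation.
#' Offsets where either side is constant are scored as missing.
#'
#' @param rdm an [build_rdm()] object or a plain numeric matrix (the total
#'   channel is used for registration).
#' @param com occupancy matrix from [build_com()]; strictly larger than the
#'   RDM in both dimensions.
#' @param z_threshold outlier z-score required to declare the registration
#'   valid (default 5).
#' @param method `"fft"` (normalized cross-correlation via FFT; used when the
#'   RDM has no missing entries) or `"direct"` (per-offset [stats::cor()]
#'   loop; always used when entries are missing).
#' @return An `m6a_registration` object: `offset` (0-based `c(row, col)`),
#'   `correlation`, `map` (full correlation map), `zscore`, `valid`,
#'   `z_threshold`.
#' @export
register_rdm_to_com <- function(rdm, com, z_threshold = 5,
                                method = c("fft", "direct")) {
  method <- match.arg(method)
  r <- if (inherits(rdm, "m6a_rdm")) rdm$total else rdm
  stopifnot(is.matrix(r), is.matrix(com))
  mr <- nrow(r); mc <- ncol(r)
  if (mr >= nrow(com) || mc >= ncol(com)) {
    stop("RDM must be strictly smaller than the COM in both dimensions",
         call. = FALSE)
  }
  if (anyNA(r)) method <- "direct"
  map <- if (method == "fft") ncc_map_fft(r, com) else ncc_map_direct(r, com)
  if (all(is.na(map))) {
    stop("correlation undefined at every offset (constant inputs?)",
         call. = FALSE)
  }
  best <- which.max(map)  # NAs never selected
  br <- (best - 1L) %% nrow(map) + 1L
  bc <- (best - 1L) %/% nrow(map) + 1L
  mu <- mean(map, na.rm = TRUE); sd_ <- stats::sd(map, na.rm = TRUE)
  z <- if (is.na(sd_) || sd_ == 0) Inf else (map[br, bc] - mu) / sd_
  structure(list(
    offset = c(row = br - 1L, col = bc - 1L),
    correlation = map[br, bc],
    map = map,
    zscore = z,
    valid = z >= z_threshold,
    z_threshold = z_threshold
  ), class = "m6a_registration")
}

# Pearson correlation at every valid offset via FFT cross-correlation with
# per-offset normalization from summed-area tables. No-NA inputs only.
ncc_map_fft <- function(r, com) {
  mr <- nrow(r); mc <- ncol(r)
  nr <- nrow(com); nc <- ncol(com)
  n <- mr * mc
  mean_r <- mean(r); ss_r <- sum((r - mean_r)^2)
  pad <- matrix(0, nr, nc)
  pad[1:mr, 1:mc] <- r
  cross <- Re(stats::fft(stats::fft(com) * Conj(stats::fft(pad)),
                         inverse = TRUE)) / (nr * nc)
  # summed-area tables for window sums of com and com^2
  win_sum <- function(m) {
    cs <- apply(apply(m, 2, cumsum), 1, cumsum)  # transposed integral image
    cs <- t(cs)
    at <- function(i, j) {
      out <- matrix(0, length(i), length(j))
      pos_i <- i > 0; pos_j <- j > 0
      if (any(pos_i) && any(pos_j)) out[pos_i, pos_j] <- cs[i[pos_i], j[pos_j]]
      out
    }
    i2 <- mr:nr; j2 <- mc:nc; i1 <- i2 - mr; j1 <- j2 - mc
    at(i2, j2) - at(i1, j2) - at(i2, j1) + at(i1, j1)
  }
  s1 <- win_sum(com)
  s2 <- win_sum(com^2)
  cross_valid <- cross[1:(nr - mr + 1), 1:(nc - mc + 1), drop = FALSE]
  num <- cross_valid - s1 * mean_r
  var_w <- s2 - s1^2 / n
  var_w[var_w < 1e-9] <- NA
  den <- sqrt(var_w * ss_r)
  out <- num / den
  out[!is.finite(out)] <- NA
  out
}

ncc_map_direct <- function(r, com) {
  mr <- nrow(r); mc <- ncol(r)
  nr <- nrow(com); nc <- ncol(com)
  map <- matrix(NA_real_, nr - mr + 1, nc - mc + 1)
  rv <- as.vector(r)
  for (i in seq_len(nrow(map))) for (j in seq_len(ncol(map))) {
    w <- as.vector(com[i:(i + mr - 1), j:(j + mc - 1)])
    ok <- !is.na(rv) & !is.na(w)
    if (sum(ok) < 3) next
    if (stats::sd(rv[ok]) == 0 || stats::sd(w[ok]) == 0) next
    map[i, j] <- stats::cor(rv[ok], w[ok])
  }
  map
}

#' @export
print.m6a_registration <- function(x, ...) {
  cat(sprintf(
    "RDM-to-COM registration: offset (%d, %d), r = %.4f, z = %.2f [%s]\n",
    x$offset[1], x$offset[2], x$correlation, x$zscore,
    if (x$valid) "valid" else sprintf("INVALID, z < %.1f", x$z_threshold)))
  invisible(x)
}

#' Tidy a registration result
#'
#' @param x an `m6a_registration`.
#' @param ... unused.
#' @return Tibble of all scored offsets with their correlation: `drow`,
#'   `dcol` (0-based), `correlation`, `is_best`.
#' @importFrom generics tidy
#' @export
tidy.m6a_registration <- function(x, ...) {
  nr <- nrow(x$map); nc <- ncol(x$map)
  tibble::tibble(
    drow = rep(0:(nr - 1), times = nc),
    dcol = rep(0:(nc - 1), each = nr),
    correlation = as.vector(x$map)
  ) |>
    dplyr::mutate(is_best = .data$drow == x$offset[1] &
                    .data$dcol == x$offset[2])
}

#' One-row summary of a registration result
#'
#' @inheritParams tidy.m6a_registration
#' @return One-row tibble: offset, correlation, z-score, validity,
#'   number of scored offsets.
#' @importFrom generics glance
#' @export
glance.m6a_registration <- function(x, ...) {
  tibble::tibble(
    drow = x$offset[1], dcol = x$offset[2],
    correlation = x$correlation, zscore = x$zscore,
    valid = x$valid, n_offsets = sum(!is.na(x$map))
  )
}

#' Link registered single cells to their molecular readout
#'
#' For every RDM position whose registered COM well contains exactly one
#' cell, joins the cell record (phenotype, channel intensities) with the
#' molecule counts of that FOV. Doublet and empty wells are excluded, as are
#' FOVs with missing counts.
#'
#' @param reg valid `m6a_registration`.
#' @param com occupancy matrix used for the registration.
#' @param cells cell tibble (with `phenotype`) from [classify_phenotype()].
#' @param rdm `m6a_rdm` with total and modification counts.
#' @return Tibble of linked single cells: `well_row`, `well_col`, `rdm_row`,
#'   `rdm_col`, `phenotype`, channel intensities, `total_count`, `m6a_count`,
#'   `m6a_level`.
#' @export
link_single_cells <- function(reg, com, cells, rdm) {
  stopifnot(inherits(reg, "m6a_registration"), inherits(rdm, "m6a_rdm"))
  if (!reg$valid) {
    stop("registration is not valid (correlation peak is not an outlier); refusing to link",
         call. = FALSE)
  }
  dr <- reg$offset[1]; dc <- reg$offset[2]
  shape <- rdm$shape
  recs <- list()
  for (i in seq_len(shape[1])) for (j in seq_len(shape[2])) {
    wr <- i + dr; wc <- j + dc
    if (is.na(rdm$total[i, j])) next
    if (com[wr, wc] != 1L) next
    cell <- cells[cells$well_row == wr & cells$well_col == wc, ]
    if (nrow(cell) != 1) next  # scan/COM disagreement; skip conservatively
    cell$rdm_row <- i; cell$rdm_col <- j
    cell$total_count <- rdm$total[i, j]
    cell$m6a_count <- rdm$modified[i, j]
    recs[[length(recs) + 1]] <- cell
  }
  if (!length(recs)) {
    out <- cells[0, ]
    out$rdm_row <- integer(); out$rdm_col <- integer()
    out$total_count <- numeric(); out$m6a_count <- numeric()
    out$m6a_level <- numeric()
    return(out)
  }
  out <- dplyr::bind_rows(recs)
  out$m6a_level <- ifelse(out$total_count > 0,
                          out$m6a_count / out$total_count, NA_real_)
  out
}
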