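#' Match spots between two channels
#'
#' One-to-one colocalization matching: all candidate pairs within `max_dist`
#' are ranked by ascending center-to-center distance and accepted greedily,
#' so each spot participates in at most one pair and every accepted pair is a
#' mutual best choice among the remaining candidates. Deterministic and
#' symmetric in its two arguments.
#'
#' @param a,b spot tibbles with `row`, `col` columns (same aligned frame).
#' @param max_dist maximum pairing distance in pixels. The pipeline uses 1 px
#'   (~100 nm) for modification calling and 2 px (~200 nm) for antibody
#'   validation.
#' @return A `spot_match` list: `pairs` tibble (`idx_a`, `idx_b`, `distance`),
#'   `unmatched_a`, `unmatched_b` integer index vectors, `max_dist`.
#' @export
match_spots <- function(a, b, max_dist = 1) {
  stopifnot(max_dist > 0)
  na <- nrow(a); nb <- nrow(b)
  pairs <- tibble::tibble(idx_a = integer(), idx_b = integer(),
                          distance = numeric())
  if (na > 0 && nb > 0) {
    # candidate pairs within max_dist
    cand <- NULL
    for (i in seq_len(na)) {
      d <- sqrt((b$row - a$row[i])^2 + (b$col - a$col[i])^2)
      j <- which(d <= max_dist)
      if (length(j)) {
        cand <- rbind(cand, cbind(i, j, d[j]))
      }
    }
    if (!is.null(cand) && nrow(cand) > 0) {
      # symmetric, deterministic ordering
      ord <- order(cand[, 3], pmin(cand[, 1], cand[, 2]),
                   pmax(cand[, 1], cand[, 2]))
      cand <- cand[ord, , drop = FALSE]
      used_a <- logical(na); used_b <- logical(nb)
      keep <- logical(nrow(cand))
      for (k in seq_len(nrow(cand))) {
        i <- cand[k, 1]; j <- cand[k, 2]
        if (!used_a[i] && !used_b[j]) {
          keep[k] <- TRUE; used_a[i] <- TRUE; used_b[j] <- TRUE
        }
      }
      cand <- cand[keep, , drop = FALSE]
      pairs <- tibble::tibble(idx_a = as.integer(cand[, 1]),
                              idx_b = as.integer(cand[, 2]),
                              distance = cand[, 3])
    }
  }
  structure(list(
    pairs = pairs,
    unmatched_a = setdiff(seq_len(na), pairs$idx_a),
    unmatched_b = setdiff(seq_len(nb), pairs$idx_b),
    max_dist = max_dist
  ), class = "spot_match")
}

#' Detection-rate metrics from a colocalization match
#'
#' The detection rate is the fraction of reference-channel molecules (e.g.
#' Cy3-labeled transcripts) that colocalize with a signal in the other
#' channel (e.g. the anti-m6A antibody complex). With per-reference-spot
#' ground-truth modification labels, also reports sensitivity (detection rate
#' on truly modified molecules) and specificity (1 - detection rate on truly
#' unmodified molecules).
#'
#' @param match a `spot_match` from [match_spots()].
#' @param n_reference number of spots in the reference (molecule) channel,
#'   i.e. set "a" of the match.
#' @param truth optional logical vector of length `n_reference`: is each
#'   reference molecule truly modified?
#' @return One-row tibble: `n_reference`, `n_matched`, `detection_rate`, and
#'   with `truth` also `sensitivity` and `specificity`.
#' @export
detection_metrics <- function(match, n_reference, truth = NULL) {
  stopifnot(inherits(match, "spot_match"))
  matched <- rep(FALSE, n_reference)
  matched[match$pairs$idx_a] <- TRUE
  if (n_reference == 0) {
    warning("empty reference set: detection rate undefined", call. = FALSE)
    rate <- NA_real_
  } else {
    rate <- mean(matched)
  }
  out <- tibble::tibble(n_reference = n_reference,
                        n_matched = sum(matched),
                        detection_rate = rate)
  if (!is.null(truth)) {
    stopifnot(length(truth) == n_reference)
    out$sensitivity <- if (any(truth)) mean(matched[truth]) else NA_real_
    out$specificity <- if (any(!truth)) 1 - mean(matched[!truth]) else NA_real_
  }
  out
}

#' Align imaging rounds on fiducial beads by phase cross-correlation
#'
#' Recovers the rigid translation between two exposures of the bead channel:
#' the normalized cross-power spectrum is inverted to a correlation surface
#' whose peak gives the integer shift, refined to sub-pixel precision by a
#' parabolic fit around the peak. Subtracting the returned `(drow, dcol)`
#' from coordinates measured in `moving` places them in the frame of
#' `reference`.
#'
#' @param moving,reference bead-channel images (same shape).
#' @param quality_floor minimum normalized correlation peak; below it the
#'   alignment is rejected with an error (guards blank rounds).
#' @param round optional round label used in error messages.
#' @return One-row tibble: `drow`, `dcol` (sub-pixel), `peak_quality`.
#' @export
align_rounds <- function(moving, reference, quality_floor = 0.05,
                         round = NULL) {
  check_image(moving, "moving"); check_image(reference, "reference")
  if (!all(dim(moving) == dim(reference))) {
    stop("images must have identical dimensions", call. = FALSE)
  }
  fr <- stats::fft(reference - mean(reference))
  fm <- stats::fft(moving - mean(moving))
  cross <- fr * Conj(fm)
  mag <- Mod(cross)
  mag[mag < .Machine$double.eps] <- .Machine$double.eps
  corr <- Re(stats::fft(cross / mag, inverse = TRUE)) / length(cross)
  nr <- nrow(corr); nc <- ncol(corr)
  pk <- which.max(corr)
  pr <- (pk - 1) %% nr + 1
  pc <- (pk - 1) %/% nr + 1
  quality <- max(min(corr[pr, pc], 1), 0)
  if (quality < quality_floor) {
    stop(sprintf("alignment failed%s: correlation peak %.3f below floor %.3f",
                 if (is.null(round)) "" else sprintf(" for round '%s'", round),
                 quality, quality_floor), call. = FALSE)
  }
  sub <- function(center, along_rows) {
    get <- function(d) {
      if (along_rows) corr[(pr - 1 + d) %% nr + 1, pc]
      else corr[pr, (pc - 1 + d) %% nc + 1]
    }
    y0 <- get(-1); y1 <- get(0); y2 <- get(1)
    den <- (y0 - 2 * y1 + y2)
    if (abs(den) < .Machine$double.eps) return(0)
    max(-0.5, min(0.5, 0.5 * (y0 - y2) / den))
  }
  dr <- (pr - 1) + sub(pr, TRUE)
  dc <- (pc - 1) + sub(pc, FALSE)
  # wrap to the symmetric range
  if (dr > nr / 2) dr <- dr - nr
  if (dc > nc / 2) dc <- dc - nc
  tibble::tibble(drow = -dr, dcol = -dc, peak_quality = quality)
}

#' Apply a round alignment offset to spot coordinates
#'
#' @param spots spot tibble with `row`, `col`.
#' @param offset one-row tibble from [align_rounds()].
#' @return The spot tibble translated into the reference frame.
#' @export
apply_offset <- function(spots, offset) {
  spots$row <- spots$row - offset$drow
  spots$col <- spots$col - offset$dcol
  spots
}
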