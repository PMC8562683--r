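#' Rolling-ball background subtraction
#'
#' Estimates a smooth background as the grayscale opening of the image with a
#' ball structuring element (erosion then dilation with height profile
#' `sqrt(radius^2 - d^2)`) and subtracts it. Diffraction-limited spots, being
#' narrower than the ball, survive essentially intact while slowly varying
#' background is removed. Borders are handled by edge replication; output is
#' clipped at zero.
#'
#' @param image numeric matrix of non-negative intensities.
#' @param radius ball radius in pixels (>= 1; must fit inside the image).
#' @return Background-subtracted matrix of the same shape.
#' @export
subtract_background <- function(image, radius = 3) {
  check_image(image)
  if (radius < 1) stop("radius must be >= 1", call. = FALSE)
  if (2 * radius + 1 > min(dim(image))) {
    stop("rolling-ball radius larger than the image", call. = FALSE)
  }
  ball <- ball_element(radius)
  bg <- morph_shift(morph_shift(image, ball, erode = TRUE), ball, erode = FALSE)
  pmax(image - bg, 0)
}

# Offsets and heights of a ball structuring element.
ball_element <- function(radius) {
  d <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  keep <- d$dr^2 + d$dc^2 <= radius^2
  d <- d[keep, ]
  d$h <- sqrt(radius^2 - d$dr^2 - d$dc^2)
  d
}

# Grayscale erosion/dilation with a non-flat element, via shifted copies of a
# replicate-padded image. O(|element|) passes of vectorized pmin/pmax.
morph_shift <- function(image, elem, erode) {
  k <- max(abs(c(elem$dr, elem$dc)))
  p <- pad_replicate(image, k)
  nr <- nrow(image); nc <- ncol(image)
  out <- NULL
  for (i in seq_len(nrow(elem))) {
    dr <- elem$dr[i]; dc <- elem$dc[i]; h <- elem$h[i]
    shifted <- p[(1 + k + dr):(nr + k + dr), (1 + k + dc):(nc + k + dc),
                 drop = FALSE]
    cand <- if (erode) shifted - h else shifted + h
    out <- if (is.null(out)) cand else if (erode) pmin(out, cand) else pmax(out, cand)
  }
  out
}

#' Gaussian smoothing
#'
#' Separable convolution with a normalized discrete Gaussian kernel
#' (half-width `ceiling(4 * sigma)`), edge-replicated at borders so constant
#' images pass through unchanged. Linear and mass-preserving away from edges.
#'
#' @param image numeric matrix.
#' @param sigma kernel standard deviation in pixels (> 0); the default 1.1
#'   matches the pipeline's pre-detection blur.
#' @return Smoothed matrix of the same shape.
#' @export
smooth_gaussian <- function(image, sigma = 1.1) {
  check_image(image)
  stopifnot(sigma > 0)
  k <- ceiling(4 * sigma)
  kern <- exp(-((-k:k)^2) / (2 * sigma^2))
  kern <- kern / sum(kern)
  p <- pad_replicate(image, k)
  nr <- nrow(image); nc <- ncol(image)
  # rows pass
  tmp <- matrix(0, nr, nc + 2L * k)
  for (i in seq_along(kern)) {
    tmp <- tmp + kern[i] * p[(i):(i + nr - 1L), , drop = FALSE]
  }
  out <- matrix(0, nr, nc)
  for (j in seq_along(kern)) {
    out <- out + kern[j] * tmp[, (j):(j + nc - 1L), drop = FALSE]
  }
  out
}

# Local maxima strictly above threshold: pixels equal to their 3x3
# neighborhood maximum. Returns a 2-column matrix of 1-based (row, col).
find_local_maxima <- function(image, threshold) {
  nr <- nrow(image); nc <- ncol(image)
  p <- pad_replicate(image, 1L)
  nbr_max <- matrix(-Inf, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nbr_max <- pmax(nbr_max,
                    p[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)])
  }
  idx <- which(image > threshold & image >= nbr_max, arr.ind = TRUE)
  # plateau de-duplication happens at the merge step
  idx
}

# Merge maxima closer than min_sep, keeping the brighter one.
merge_maxima <- function(peaks, values, min_sep = 2) {
  if (nrow(peaks) <= 1) return(peaks)
  ord <- order(-values, peaks[, 1], peaks[, 2])
  peaks <- peaks[ord, , drop = FALSE]
  keep <- logical(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    if (i == 1) { keep[1] <- TRUE; next }
    kept <- peaks[keep, , drop = FALSE]
    d2 <- (kept[, 1] - peaks[i, 1])^2 + (kept[, 2] - peaks[i, 2])^2
    keep[i] <- all(d2 > min_sep^2)
  }
  peaks[keep, , drop = FALSE]
}

#' Data-driven detection threshold
#'
#' Robust estimate of a pixel threshold for maxima detection on a processed
#' (background-subtracted, smoothed) image: `median + k * MAD`.
#'
#' @param image processed image matrix.
#' @param k number of MADs above the median (default 5).
#' @return A single threshold value.
#' @export
estimate_threshold <- function(image, k = 5) {
  check_image(image)
  stats::median(image) + k * stats::mad(image)
}

#' Sub-pixel 2D Gaussian fit at a candidate peak
#'
#' Least-squares fit of an isotropic 2D Gaussian plus constant local
#' background, `A * exp(-((r - r0)^2 + (c - c0)^2) / (2 s^2)) + b`, over a
#' square window centered on an integer peak (Levenberg-Marquardt). Windows
#' are clipped at image borders; a clipped window smaller than 3x3 or a
#' non-converging fit yields a flagged row rather than an error.
#'
#' @param image numeric matrix (typically background-subtracted).
#' @param peak integer `c(row, col)` of the candidate maximum, 0-based.
#' @param window fit half-width in pixels (window is `2*window+1` square).
#' @return One-row tibble: `row`, `col` (0-based sub-pixel center),
#'   `amplitude`, `sigma`, `background`, `fit_rss`, `status` ("ok"/"failed").
#' @export
fit_gaussian_2d <- function(image, peak, window = 3L) {
  check_image(image)
  pr <- as.integer(round(peak[1])) + 1L  # to 1-based matrix index
  pc <- as.integer(round(peak[2])) + 1L
  nr <- nrow(image); nc <- ncol(image)
  if (pr < 1 || pr > nr || pc < 1 || pc > nc) {
    stop("peak outside image", call. = FALSE)
  }
  r1 <- max(1L, pr - window); r2 <- min(nr, pr + window)
  c1 <- max(1L, pc - window); c2 <- min(nc, pc + window)
  failed <- function() tibble::tibble(
    row = pr - 1, col = pc - 1, amplitude = NA_real_, sigma = NA_real_,
    background = NA_real_, fit_rss = NA_real_, status = "failed")
  if (r2 - r1 < 2 || c2 - c1 < 2) return(failed())
  win <- image[r1:r2, c1:c2]
  df <- data.frame(
    r = rep((r1:r2) - 1, times = c2 - c1 + 1),
    c = rep((c1:c2) - 1, each = r2 - r1 + 1),
    z = as.vector(win)
  )
  b0 <- min(df$z)
  a0 <- max(df$z) - b0
  if (a0 <= 0) return(failed())
  fit <- tryCatch(
    suppressWarnings(minpack.lm::nlsLM(
      z ~ A * exp(-((r - r0)^2 + (c - c0)^2) / (2 * s^2)) + b,
      data = df,
      start = list(A = a0, r0 = pr - 1, c0 = pc - 1, s = 1.3, b = b0),
      lower = c(A = 1e-9, r0 = r1 - 2, c0 = c1 - 2, s = 0.3, b = -Inf),
      upper = c(A = Inf, r0 = r2, c0 = c2, s = 2 * window, b = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )),
    error = function(e) NULL
  )
  if (is.null(fit)) return(failed())
  cf <- stats::coef(fit)
  if (!all(is.finite(cf)) || cf[["s"]] <= 0 || cf[["A"]] <= 0) return(failed())
  # parameters pinned to the box or an exhausted iteration budget both mean
  # the optimizer did not settle on an interior optimum
  if (isFALSE(fit$convInfo$isConv) &&
      (cf[["r0"]] <= r1 - 2 || cf[["r0"]] >= r2 ||
       cf[["c0"]] <= c1 - 2 || cf[["c0"]] >= c2)) {
    return(failed())
  }
  tibble::tibble(
    row = cf[["r0"]], col = cf[["c0"]], amplitude = cf[["A"]],
    sigma = cf[["s"]], background = cf[["b"]],
    fit_rss = sum(stats::resid(fit)^2), status = "ok"
  )
}

#' Detect single-molecule spots in an image
#'
#' The full detection chain: rolling-ball background subtraction, Gaussian
#' blur, local maxima strictly above a pixel threshold, duplicate-maxima
#' merging (keep the brighter within `min_sep`), then a sub-pixel 2D Gaussian
#' fit at each maximum on the background-subtracted image. Failed fits are
#' returned flagged, never silently dropped.
#'
#' @param image numeric intensity matrix.
#' @param threshold pixel threshold applied to the processed image; when
#'   `NULL`, estimated by [estimate_threshold()].
#' @param radius rolling-ball radius in pixels.
#' @param sigma Gaussian blur sigma in pixels.
#' @param min_sep merge radius for duplicate maxima (pixels).
#' @param window Gaussian fit half-width.
#' @param threshold_k MAD multiplier when estimating the threshold.
#' @return Tibble of spots (0-based `row`, `col`, `amplitude`, `sigma`,
#'   `background`, `fit_rss`, `status`), with the threshold used attached as
#'   attribute `"threshold"`.
#' @export
detect_spots <- function(image, threshold = NULL, radius = 3, sigma = 1.1,
                         min_sep = 2, window = 3L, threshold_k = 5) {
  check_image(image)
  sub <- subtract_background(image, radius = radius)
  sm <- smooth_gaussian(sub, sigma = sigma)
  if (is.null(threshold)) threshold <- estimate_threshold(sm, k = threshold_k)
  if (threshold < 0) stop("threshold must be >= 0", call. = FALSE)
  peaks <- find_local_maxima(sm, threshold)
  if (nrow(peaks) == 0) {
    out <- empty_spot_tibble()
    attr(out, "threshold") <- threshold
    return(out)
  }
  peaks <- merge_maxima(peaks, sm[peaks], min_sep = min_sep)
  fits <- lapply(seq_len(nrow(peaks)), function(i) {
    fit_gaussian_2d(sub, c(peaks[i, 1] - 1L, peaks[i, 2] - 1L), window = window)
  })
  out <- dplyr::bind_rows(fits)
  # fits of neighboring maxima can converge to the same center; keep brighter
  out <- dplyr::arrange(out, dplyr::desc(dplyr::coalesce(.data$amplitude, 0)))
  dup <- duplicated(round(cbind(out$row, out$col), 3))
  out <- out[!dup, ]
  out <- dplyr::arrange(out, .data$row, .data$col)
  attr(out, "threshold") <- threshold
  out
}
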