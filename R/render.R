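#' CCD noise model
#'
#' Standard camera model for rendered images: a constant additive background,
#' Poisson shot noise applied to (background + signal) photons, then Gaussian
#' read noise. Set `shot_noise = FALSE` and `read_noise_sd = 0` for noiseless
#' renders.
#'
#' @param background_level background in counts (>= 0).
#' @param photon_gain counts per photon (> 0).
#' @param read_noise_sd read-noise standard deviation in counts (>= 0).
#' @param shot_noise apply Poisson shot noise?
#' @return A `noise_model` list.
#' @export
noise_model <- function(background_level = 100, photon_gain = 1,
                        read_noise_sd = 2, shot_noise = TRUE) {
  stopifnot(background_level >= 0, photon_gain > 0, read_noise_sd >= 0)
  structure(list(background_level = background_level,
                 photon_gain = photon_gain,
                 read_noise_sd = read_noise_sd,
                 shot_noise = isTRUE(shot_noise)),
            class = "noise_model")
}

# Pixel-integrated 2D Gaussian profile of one spot added onto `img`.
# Coordinates are 0-based with the origin at the center of the top-left pixel;
# matrix row i covers coordinate [i - 1.5, i - 0.5] in 1-based indexing.
add_spot <- function(img, row, col, amplitude, sigma) {
  nr <- nrow(img); nc <- ncol(img)
  k <- ceiling(4 * sigma)
  r1 <- max(1L, floor(row + 1 - k)); r2 <- min(nr, ceiling(row + 1 + k))
  c1 <- max(1L, floor(col + 1 - k)); c2 <- min(nc, ceiling(col + 1 + k))
  if (r1 > r2 || c1 > c2) return(img)
  # integral of the unit-peak Gaussian over pixel [x-0.5, x+0.5], rescaled so
  # the value at the exact center pixel is ~amplitude
  ir <- sigma * sqrt(2 * pi) *
    (stats::pnorm(((r1:r2) - 1 + 0.5 - row) / sigma) -
       stats::pnorm(((r1:r2) - 1 - 0.5 - row) / sigma))
  ic <- sigma * sqrt(2 * pi) *
    (stats::pnorm(((c1:c2) - 1 + 0.5 - col) / sigma) -
       stats::pnorm(((c1:c2) - 1 - 0.5 - col) / sigma))
  img[r1:r2, c1:c2] <- img[r1:r2, c1:c2] + amplitude * outer(ir, ic)
  img
}

#' Render a single-molecule field of view
#'
#' Forward model for a TIRF exposure: each spot is drawn as a pixel-integrated
#' 2D Gaussian point-spread function at its sub-pixel center, a constant
#' background is added, and camera noise (Poisson shot + Gaussian read noise)
#' is applied. One image is returned per channel present in `spots`.
#'
#' @param spots tibble with columns `row`, `col` (0-based sub-pixel centers),
#'   `amplitude` (peak counts) and optionally `channel`. May have zero rows.
#' @param shape image dimensions `c(rows, cols)` in pixels.
#' @param psf_sigma Gaussian PSF width in pixels (> 0).
#' @param noise a [noise_model()].
#' @param seed integer seed; renders are bit-identical per seed.
#' @param channels channel names to render even when empty (e.g. a blank
#'   channel); defaults to those present in `spots`.
#' @return Named list of numeric matrices, one per channel.
#' @export
render_fov <- function(spots, shape, psf_sigma = 1.3, noise = noise_model(),
                       seed = NULL, channels = NULL) {
  stopifnot(length(shape) == 2L)
  if (any(shape <= 0)) stop("image shape must be positive", call. = FALSE)
  stopifnot(psf_sigma > 0, inherits(noise, "noise_model"))
  if (nrow(spots) > 0) {
    if (!"channel" %in% names(spots)) spots$channel <- "ch1"
    bad <- spots$row < 0 | spots$row > shape[1] - 1 |
      spots$col < 0 | spots$col > shape[2] - 1
    if (any(bad)) stop("spot centers outside image bounds", call. = FALSE)
  }
  channels <- channels %||%
    (if (nrow(spots) > 0) unique(spots$channel) else "ch1")
  with_seed(seed, {
    out <- lapply(channels, function(ch) {
      img <- matrix(0, shape[1], shape[2])
      sub <- if (nrow(spots) > 0) spots[spots$channel == ch, ] else spots
      if (nrow(sub) > 0) {
        for (i in seq_len(nrow(sub))) {
          img <- add_spot(img, sub$row[i], sub$col[i], sub$amplitude[i],
                          psf_sigma)
        }
      }
      img <- img + noise$background_level
      if (noise$shot_noise) {
        img[] <- noise$photon_gain *
          stats::rpois(length(img), lambda = pmax(img, 0) / noise$photon_gain)
      }
      if (noise$read_noise_sd > 0) {
        img[] <- img + stats::rnorm(length(img), sd = noise$read_noise_sd)
      }
      pmax(img, 0)
    })
    names(out) <- channels
    out
  })
}
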