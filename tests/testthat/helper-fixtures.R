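# Shared fixtures: all synthetic, built in code at test time.

noiseless <- function(background = 0) {
  noise_model(background_level = background, photon_gain = 1,
              read_noise_sd = 0, shot_noise = FALSE)
}

# Render one or more spots without noise.
render_clean <- function(spots, shape = c(64, 64), psf_sigma = 1.3,
                         background = 0) {
  if (!"channel" %in% names(spots)) spots$channel <- "a"
  render_fov(spots, shape = shape, psf_sigma = psf_sigma,
             noise = noiseless(background))[[1]]
}

# Draw n random spot centers with a minimum separation, 0-based coords.
random_centers <- function(n, shape, min_sep, margin = 5) {
  rows <- numeric(0); cols <- numeric(0)
  while (length(rows) < n) {
    r <- runif(1, margin, shape[1] - 1 - margin)
    c <- runif(1, margin, shape[2] - 1 - margin)
    if (length(rows) == 0 || all((rows - r)^2 + (cols - c)^2 > min_sep^2)) {
      rows <- c(rows, r); cols <- c(cols, c)
    }
  }
  tibble::tibble(row = rows, col = cols)
}

# A small 2-phenotype simulation configuration used across tests.
small_sim_config <- function(...) {
  sim_config(com_shape = c(20, 30), rdm_shape = c(6, 9), well_pitch = 8,
             loading_rate = 0.4, mean_molecules = 220, ...)
}

# Default gates separating the two simulated stains on channel 1.
default_gates <- function() {
  tibble::tibble(phenotype = c("K562", "YAC1"), channel = c("ch1", "ch1"),
                 min = c(400, 0), max = c(Inf, 399))
}
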