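# Shared fixtures, all generated in code at test time.

# Small flat test image with a given tilt/center.
flat_image <- function(size = 64L, value = 0, tilt_deg = 0,
                       center = NULL, beamstop = NULL) {
  if (is.null(center)) center <- rep((size - 1) / 2, 2)
  tilt_image(matrix(value, size, size), tilt_deg, center, beamstop)
}

test_config <- function(wavelength = 0.0251, c_px = 4345, size = 1024L) {
  instrument_config(wavelength, c_px, c(size, size))
}

# Deposit a pixel-integrated Gaussian on an image matrix (0-based x, y).
add_gaussian <- function(pixels, x, y, sigma, intensity) {
  ix <- 0:(ncol(pixels) - 1); iy <- 0:(nrow(pixels) - 1)
  fx <- pnorm(ix + 0.5, x, sigma) - pnorm(ix - 0.5, x, sigma)
  fy <- pnorm(iy + 0.5, y, sigma) - pnorm(iy - 0.5, y, sigma)
  pixels + intensity * (fy %o% fx)
}

# Compact tilt series: orthorhombic 40/60/90 px cell on 512 px stills
# (over a +/-35 degree range so the l = +/-1 layers, reachable only at
# detector radii beyond ~160 px, are well sampled).
mini_spec <- function(seed = 11L, noise = "poisson", n_tilts = 13L) {
  basis <- diag(c(40, 60, 90))
  basis <- basis %*% t(microedr:::sim_rotation(2, 0) %*%
                         microedr:::sim_rotation(-3, 90))
  simulation_spec(
    basis = basis,
    tilt_angles = seq(-35, 35, length.out = n_tilts),
    config = instrument_config(0.0251, 1000, c(512L, 512L)),
    psf_sigma = 1.2,
    background = 40,
    noise = noise,
    beamstop = list(center = c(255.5, 255.5), radius = 20),
    partiality_width = 1.2,
    intensity_meanlog = log(8000),
    intensity_sdlog = 0.6,
    seed = seed)
}

mini_truth_basis <- function() mini_spec()$basis
mini_resolution <- 2.9  # angstrom; prediction radius ~345 px at c = 1000

mini_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "microedr-mini")
      sim <- simulate_tilt_series(mini_spec(), dir)
      make_pick_files(sim$truth, dir, n_picks = 130, jitter_px = 0.3,
                      seed = 12L)
      cache <<- list(dir = dir, sim = sim, spec = mini_spec())
    }
    cache
  }
})
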