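# The simulator keeps its own geometry (rotation built here, sphere distance
# as radial distance to the sphere surface) so that agreement with the
# analysis transform chain is a genuine round-trip test, not a tautology.

sim_rotation <- function(theta_deg, axis_deg = 90) {
  th <- theta_deg * pi / 180
  ph <- axis_deg * pi / 180
  u <- c(cos(ph), sin(ph), 0)
  K <- matrix(c(0, -u[3], u[2],
                u[3], 0, -u[1],
                -u[2], u[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Specification of a synthetic MicroED tilt series
#'
#' The defaults emulate the pixel regime of a tetragonal lysozyme-like
#' crystal: reciprocal cell lengths 55, 55, 112 px with 90 degree angles,
#' 20 still patterns over a -20..20 degree tilt range, a 200 kV wavelength
#' and a camera constant placing the image edge near 8.5 Å. The lattice is
#' given a small fixed misorientation so that no axis lies exactly in the
#' detector plane.
#'
#' @param basis 3 x 3 true reciprocal basis (rows a*, b*, c*, px).
#' @param tilt_angles Tilt angles in degrees.
#' @param config An [instrument_config()].
#' @param psf_sigma Gaussian spot width in px.
#' @param background Mean background level in counts.
#' @param noise `"poisson"` (counts drawn from Poisson with the expected
#'   value as mean) or `"none"` (expected values, rounded).
#' @param beamstop `list(center, radius)` shadow, or NULL; the default masks
#'   a 40 px circle at the beam center.
#' @param partiality_width Gaussian width (px) of the intensity attenuation
#'   with distance from the Ewald sphere.
#' @param intensity_meanlog,intensity_sdlog Log-normal parameters of the
#'   full (complete-reflection) intensities, in summed counts.
#' @param render_floor Lattice points whose attenuated intensity falls below
#'   this many counts are left out of the image and the truth table.
#' @param seed Integer seed; a fixed seed makes the output byte-identical.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(basis = NULL,
                            tilt_angles = seq(-20, 20, length.out = 20),
                            config = instrument_config(
                              wavelength = 0.0251,
                              px_per_inv_angstrom = 4345,
                              image_size = c(1024L, 1024L)),
                            psf_sigma = 1.5,
                            background = 50,
                            noise = c("poisson", "none"),
                            beamstop = list(center = c(511.5, 511.5),
                                            radius = 40),
                            partiality_width = 1.5,
                            intensity_meanlog = log(2e4),
                            intensity_sdlog = 0.7,
                            render_floor = 1,
                            seed = 42L) {
  if (is.null(basis)) {
    # tetragonal 55/55/112 px cell, tipped by a few degrees off the axes
    basis <- diag(c(55, 55, 112))
    basis <- basis %*% t(sim_rotation(2, axis_deg = 0) %*%
                           sim_rotation(-3, axis_deg = 90))
  }
  structure(list(basis = basis, tilt_angles = tilt_angles, config = config,
                 psf_sigma = psf_sigma, background = background,
                 noise = match.arg(noise), beamstop = beamstop,
                 partiality_width = partiality_width,
                 intensity_meanlog = intensity_meanlog,
                 intensity_sdlog = intensity_sdlog,
                 render_floor = render_floor, seed = as.integer(seed)),
            class = "simulation_spec")
}

# Add a pixel-integrated 2D Gaussian of total `intensity` at 0-based (x, y).
render_gaussian <- function(pixels, x, y, sigma, intensity) {
  r <- ceiling(4 * sigma) + 1L
  nx <- ncol(pixels); ny <- nrow(pixels)
  ix <- max(0L, floor(x) - r):min(nx - 1L, ceiling(x) + r)
  iy <- max(0L, floor(y) - r):min(ny - 1L, ceiling(y) + r)
  if (!length(ix) || !length(iy)) return(pixels)
  fx <- stats::pnorm(ix + 0.5, x, sigma) - stats::pnorm(ix - 0.5, x, sigma)
  fy <- stats::pnorm(iy + 0.5, y, sigma) - stats::pnorm(iy - 0.5, y, sigma)
  pixels[iy + 1L, ix + 1L] <- pixels[iy + 1L, ix + 1L] +
    intensity * (fy %o% fx)
  pixels
}

#' Render a synthetic tilt series with ground truth
#'
#' For each tilt angle, every reciprocal-lattice point within the detector
#' field is tested against the exact Ewald sphere; its full intensity is
#' attenuated by a Gaussian in the point's distance from the sphere surface
#' (the partiality model), and surviving spots are rendered as
#' pixel-integrated Gaussians over a noisy background with a beamstop
#' shadow. Images are written as 16-bit grayscale TIFFs alongside a dataset
#' YAML config and a tab-separated ground-truth table.
#'
#' @param spec A [simulation_spec()].
#' @param dir Output directory (created if needed).
#' @return List with `image_paths`, `config_path`, `truth_path`, and `truth`
#'   — a data frame with one row per rendered reflection: `file`,
#'   `tilt_deg`, `h k l`, `x y` (true 0-based detector position), `eps_px`
#'   (signed distance from the Ewald sphere), `I_full`, `I_partial`,
#'   `masked` (under the beamstop).
#' @export
simulate_tilt_series <- function(spec, dir) {
  stopifnot(inherits(spec, "simulation_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed)
  cfg <- spec$config
  nx <- cfg$image_size[1]; ny <- cfg$image_size[2]
  center <- c((nx - 1) / 2, (ny - 1) / 2)
  RE <- cfg$px_per_inv_angstrom / cfg$wavelength
  r_max <- sqrt(sum(pmax(center, c(nx - 1, ny - 1) - center)^2))

  # enumerate lattice points once, with reproducible full intensities
  nrm <- sqrt(rowSums(spec$basis^2))
  hmax <- ceiling(r_max / nrm)
  grid <- as.matrix(expand.grid(h = -hmax[1]:hmax[1], k = -hmax[2]:hmax[2],
                                l = -hmax[3]:hmax[3]))
  p <- grid %*% spec$basis
  keep <- rowSums(p^2) <= r_max^2 & rowSums(abs(grid)) > 0
  grid <- grid[keep, , drop = FALSE]; p <- p[keep, , drop = FALSE]
  # Friedel symmetry: mates share one full intensity
  key <- apply(grid, 1L, function(h) {
    s <- if (h[1] < 0 || (h[1] == 0 && h[2] < 0) ||
             (h[1] == 0 && h[2] == 0 && h[3] < 0)) -h else h
    paste(s, collapse = ",")
  })
  ukey <- unique(key)
  Iu <- stats::rlnorm(length(ukey), spec$intensity_meanlog,
                      spec$intensity_sdlog)
  I_full <- Iu[match(key, ukey)]

  image_rows <- list(); truth_rows <- list(); paths <- character(0)
  for (i in seq_along(spec$tilt_angles)) {
    th <- spec$tilt_angles[i]
    Rm <- sim_rotation(th, cfg$tilt_axis_deg)
    u <- p %*% Rm  # lab -> image frame (rows: R(-theta) p)
    # signed distance from the sphere surface (center at z = +RE)
    eps <- RE - sqrt(u[, 1]^2 + u[, 2]^2 + (u[, 3] - RE)^2)
    att <- exp(-eps^2 / (2 * spec$partiality_width^2))
    Ipart <- I_full * att
    sel <- which(Ipart >= spec$render_floor)
    x <- u[sel, 1] + center[1]; y <- u[sel, 2] + center[2]
    inb <- x >= 0 & x <= nx - 1 & y >= 0 & y <= ny - 1
    sel <- sel[inb]; x <- x[inb]; y <- y[inb]

    px <- matrix(spec$background, nrow = ny, ncol = nx)
    for (s in seq_along(sel)) {
      px <- render_gaussian(px, x[s], y[s], spec$psf_sigma, Ipart[sel[s]])
    }
    if (spec$noise == "poisson") {
      px <- matrix(stats::rpois(length(px), px), nrow = ny)
    } else {
      px <- round(px)
    }
    masked <- rep(FALSE, length(sel))
    if (!is.null(spec$beamstop)) {
      bs <- spec$beamstop
      gx <- matrix(0:(nx - 1), ny, nx, byrow = TRUE)
      gy <- matrix(0:(ny - 1), ny, nx)
      px[(gx - bs$center[1])^2 + (gy - bs$center[2])^2 <= bs$radius^2] <- 0
      masked <- (x - bs$center[1])^2 + (y - bs$center[2])^2 <= bs$radius^2
    }
    file <- sprintf("image_%03d.tif", i)
    write_tiff_counts(px, file.path(dir, file))
    paths <- c(paths, file.path(dir, file))
    image_rows[[i]] <- data.frame(
      file = file, tilt_deg = th, center_x = center[1], center_y = center[2],
      beamstop_x = if (is.null(spec$beamstop)) NA_real_ else spec$beamstop$center[1],
      beamstop_y = if (is.null(spec$beamstop)) NA_real_ else spec$beamstop$center[2],
      beamstop_r = if (is.null(spec$beamstop)) NA_real_ else spec$beamstop$radius,
      stringsAsFactors = FALSE)
    if (length(sel)) {
      truth_rows[[i]] <- data.frame(
        file = file, tilt_deg = th, h = grid[sel, 1], k = grid[sel, 2],
        l = grid[sel, 3], x = x, y = y, eps_px = eps[sel],
        I_full = I_full[sel], I_partial = Ipart[sel], masked = masked,
        stringsAsFactors = FALSE)
    }
  }
  images <- do.call(rbind, image_rows)
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  config_path <- file.path(dir, "dataset.yaml")
  write_dataset_config(cfg, images, config_path)
  truth_path <- file.path(dir, "ground_truth.tsv")
  utils::write.table(truth, truth_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  list(image_paths = paths, config_path = config_path,
       truth_path = truth_path, truth = truth)
}

#' Emulate user spot picking from a simulated ground truth
#'
#' Samples bright rendered reflections (distinct Miller indices, as a
#' careful user avoids picking the same low-angle reflection on several
#' patterns), jitters their positions, and writes one pick file per image.
#' The zero-most-tilt image receives Friedel-pair picks for beam-center
#' determination, and every image receives two reference picks: bright
#' reflections close to the exact Ewald sphere with non-collinear indices.
#'
#' @param truth Ground-truth table from [simulate_tilt_series()].
#' @param dir Directory for the pick files (named `<image stem>_picks.txt`).
#' @param n_picks Total picks across all images (default 300).
#' @param jitter_px Standard deviation of the positional jitter (default
#'   0.3 px).
#' @param seed Integer seed.
#' @return List `paths` (named by image file) and `picks` (the combined
#'   table with columns `file`, `x`, `y`, `role`).
#' @export
make_pick_files <- function(truth, dir, n_picks = 300, jitter_px = 0.3,
                            seed = 7L) {
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  avail <- truth[!truth$masked, ]
  # one appearance per distinct index: keep the brightest rendering
  ord <- order(-avail$I_partial)
  avail <- avail[ord, ]
  avail <- avail[!duplicated(avail[, c("h", "k", "l")]), ]
  if (n_picks > nrow(avail)) {
    stop("requested ", n_picks, " picks but only ", nrow(avail),
         " distinct rendered reflections are available")
  }
  sel <- avail[sample.int(nrow(avail), n_picks,
                          prob = avail$I_partial / sum(avail$I_partial)), ]
  picks <- data.frame(file = sel$file,
                      x = sel$x + stats::rnorm(n_picks, 0, jitter_px),
                      y = sel$y + stats::rnorm(n_picks, 0, jitter_px),
                      role = "pick", stringsAsFactors = FALSE)

  # Reference spots: per image, bright and on-sphere, and — emulating the
  # visual-inspection loop a user runs on the prediction overlay — the pair
  # whose (gcd-reduced) check vector is lowest-order, so both references
  # come from the same fundamental Laue band and the predicted zones have
  # their full width. Mixed-band pairs give a fine plane family and
  # visibly poor prediction.
  for (f in unique(truth$file)) {
    tf <- truth[truth$file == f & !truth$masked, ]
    tf <- tf[abs(tf$eps_px) <= 1 & tf$x >= 6 & tf$y >= 6, ]
    tf <- tf[order(-tf$I_partial), ]
    if (nrow(tf) < 2L) next
    tf <- tf[seq_len(min(12L, nrow(tf))), ]
    best <- NULL
    for (a in seq_len(nrow(tf) - 1L)) for (b in (a + 1L):nrow(tf)) {
      q <- compute_check_vector_safe(c(tf$h[a], tf$k[a], tf$l[a]),
                                     c(tf$h[b], tf$k[b], tf$l[b]))
      if (is.null(q)) next
      q <- q / gcd3(q)
      sc <- sum(q^2)
      if (is.null(best) || sc < best$sc) best <- list(a = a, b = b, sc = sc)
    }
    if (is.null(best)) next
    rr <- tf[c(best$a, best$b), ]
    picks <- rbind(picks, data.frame(
      file = f, x = rr$x + stats::rnorm(2, 0, jitter_px),
      y = rr$y + stats::rnorm(2, 0, jitter_px), role = "reference",
      stringsAsFactors = FALSE))
  }

  # Friedel pairs on the image(s) closest to zero tilt
  f0 <- truth$file[which.min(abs(truth$tilt_deg))]
  t0 <- truth[truth$file == f0 & !truth$masked, ]
  npairs <- 0L
  for (r in seq_len(nrow(t0))) {
    if (npairs >= 2L) break
    mate <- which(t0$h == -t0$h[r] & t0$k == -t0$k[r] & t0$l == -t0$l[r])
    if (length(mate) && (t0$h[r] > 0 || (t0$h[r] == 0 && t0$k[r] > 0))) {
      pr <- t0[c(r, mate[1]), ]
      picks <- rbind(picks, data.frame(
        file = f0, x = pr$x + stats::rnorm(2, 0, jitter_px),
        y = pr$y + stats::rnorm(2, 0, jitter_px), role = "friedel",
        stringsAsFactors = FALSE))
      npairs <- npairs + 1L
    }
  }

  paths <- character(0)
  for (f in unique(picks$file)) {
    path <- file.path(dir, sub("\\.tif$", "_picks.txt", f))
    write_spot_picks(picks[picks$file == f, c("x", "y", "role")], path)
    paths[f] <- path
  }
  list(paths = paths, picks = picks)
}

# compute_check_vector without erroring on collinear input
compute_check_vector_safe <- function(h1, h2) {
  tryCatch(compute_check_vector(h1, h2), error = function(e) NULL)
}

gcd3 <- function(q) {
  gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)
  Reduce(gcd2, abs(q[q != 0]))
}
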