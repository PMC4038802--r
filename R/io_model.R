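#' Instrument configuration
#'
#' Bundles the microscope/camera constants needed to interpret a diffraction
#' pattern: the electron wavelength and the camera conversion factor that maps
#' reciprocal ångström to detector pixels.
#'
#' @param wavelength Electron wavelength λ in Å (e.g. 0.0251 Å at 200 kV).
#' @param px_per_inv_angstrom Camera conversion factor c in px·Å: a reflection
#'   at resolution d Å falls at radius `px_per_inv_angstrom / d` pixels from
#'   the beam center.
#' @param image_size Integer vector `c(nx, ny)`: raster width and height in px.
#' @param tilt_axis_deg In-plane angle of the goniometer tilt axis on the
#'   detector, degrees from the +x axis. Default 90 (the image y axis).
#'
#' @return An object of class `instrument_config`.
#' @export
instrument_config <- function(wavelength, px_per_inv_angstrom,
                              image_size = c(1024L, 1024L),
                              tilt_axis_deg = 90) {
  stopifnot(is.numeric(wavelength), length(wavelength) == 1L, wavelength > 0,
            is.numeric(px_per_inv_angstrom), length(px_per_inv_angstrom) == 1L,
            px_per_inv_angstrom > 0,
            length(image_size) == 2L, all(image_size > 0))
  structure(list(wavelength = wavelength,
                 px_per_inv_angstrom = px_per_inv_angstrom,
                 image_size = as.integer(image_size),
                 tilt_axis_deg = tilt_axis_deg),
            class = "instrument_config")
}

#' Resolution (Å) at a detector radius
#'
#' @param r_px Radius from the beam center in pixels.
#' @param config An [instrument_config()].
#' @return Resolution in Å (`px_per_inv_angstrom / r_px`).
#' @export
resolution_at_radius <- function(r_px, config) {
  config$px_per_inv_angstrom / r_px
}

#' Detector radius (px) at a resolution
#'
#' @param d_angstrom Resolution in Å.
#' @param config An [instrument_config()].
#' @return Radius in pixels.
#' @export
radius_at_resolution <- function(d_angstrom, config) {
  config$px_per_inv_angstrom / d_angstrom
}

#' A single still diffraction pattern of a tilt series
#'
#' @param pixels Numeric matrix of non-negative counts, indexed
#'   `pixels[y + 1, x + 1]` for 0-based pixel coordinates (x = column
#'   rightward, y = row downward, origin top-left).
#' @param tilt_deg Goniometer tilt angle θ in degrees, in \[-90, 90\].
#' @param beam_center Numeric `c(x, y)` of the unscattered beam, 0-based px.
#' @param beamstop Optional `list(center = c(x, y), radius = r)` circular mask.
#' @param id Optional identifier (defaults to the tilt angle as a string).
#'
#' @return An object of class `tilt_image`.
#' @export
tilt_image <- function(pixels, tilt_deg, beam_center, beamstop = NULL,
                       id = NULL) {
  stopifnot(is.matrix(pixels), all(pixels >= 0),
            length(tilt_deg) == 1L, tilt_deg >= -90, tilt_deg <= 90,
            length(beam_center) == 2L)
  nx <- ncol(pixels); ny <- nrow(pixels)
  if (beam_center[1] < 0 || beam_center[1] > nx - 1 ||
      beam_center[2] < 0 || beam_center[2] > ny - 1) {
    stop("beam_center (", beam_center[1], ", ", beam_center[2],
         ") lies outside the ", nx, "x", ny, " raster")
  }
  if (!is.null(beamstop)) {
    stopifnot(is.list(beamstop), length(beamstop$center) == 2L,
              beamstop$radius >= 0)
  }
  structure(list(pixels = pixels, tilt_deg = tilt_deg,
                 beam_center = as.numeric(beam_center), beamstop = beamstop,
                 id = if (is.null(id)) sprintf("tilt_%+.1f", tilt_deg) else id),
            class = "tilt_image")
}

#' @export
print.tilt_image <- function(x, ...) {
  cat(sprintf("<tilt_image %s: %dx%d px, tilt %+.2f deg, center (%.1f, %.1f)%s>\n",
              x$id, ncol(x$pixels), nrow(x$pixels), x$tilt_deg,
              x$beam_center[1], x$beam_center[2],
              if (is.null(x$beamstop)) "" else ", beamstop"))
  invisible(x)
}

#' Test whether 0-based pixel coordinates fall under the beamstop mask
#'
#' @param xy Numeric vector `c(x, y)` or an n x 2 matrix of positions.
#' @param image A [tilt_image()].
#' @return Logical vector.
#' @export
under_beamstop <- function(xy, image) {
  xy <- rbind_xy(xy)
  if (is.null(image$beamstop)) return(rep(FALSE, nrow(xy)))
  ctr <- image$beamstop$center
  sqrt((xy[, 1] - ctr[1])^2 + (xy[, 2] - ctr[2])^2) <= image$beamstop$radius
}

# Coerce c(x, y) or an n x 2 matrix/data.frame to an n x 2 numeric matrix.
rbind_xy <- function(xy) {
  if (is.data.frame(xy)) xy <- as.matrix(xy)
  if (!is.matrix(xy)) xy <- matrix(as.numeric(xy), ncol = 2L)
  storage.mode(xy) <- "double"
  xy
}

#' Read a dataset configuration file
#'
#' The dataset config is a YAML file holding the instrument constants and the
#' per-image acquisition metadata (file name, tilt angle, beam center, optional
#' beamstop), so that angles reported by the microscope stage can be inspected
#' and edited as plain text.
#'
#' @param path Path to the YAML config.
#' @return `list(config = instrument_config, images = data.frame)` where the
#'   data frame has columns `file`, `tilt_deg`, `center_x`, `center_y` and
#'   optional `beamstop_x`, `beamstop_y`, `beamstop_r`.
#' @export
read_dataset_config <- function(path) {
  if (!file.exists(path)) stop("dataset config not found: ", path)
  y <- yaml::read_yaml(path)
  cfg <- instrument_config(
    wavelength = y$instrument$wavelength,
    px_per_inv_angstrom = y$instrument$px_per_inv_angstrom,
    image_size = as.integer(unlist(y$instrument$image_size)),
    tilt_axis_deg = if (is.null(y$instrument$tilt_axis_deg)) 90
                    else y$instrument$tilt_axis_deg)
  imgs <- do.call(rbind, lapply(y$images, function(im) {
    data.frame(file = im$file, tilt_deg = im$tilt_deg,
               center_x = im$beam_center[[1]], center_y = im$beam_center[[2]],
               beamstop_x = if (is.null(im$beamstop)) NA_real_ else im$beamstop$center[[1]],
               beamstop_y = if (is.null(im$beamstop)) NA_real_ else im$beamstop$center[[2]],
               beamstop_r = if (is.null(im$beamstop)) NA_real_ else im$beamstop$radius,
               stringsAsFactors = FALSE)
  }))
  list(config = cfg, images = imgs)
}

#' Write a dataset configuration file
#'
#' @param config An [instrument_config()].
#' @param images Data frame as returned in [read_dataset_config()]'s `images`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dataset_config <- function(config, images, path) {
  y <- list(
    instrument = list(wavelength = config$wavelength,
                      px_per_inv_angstrom = config$px_per_inv_angstrom,
                      image_size = as.integer(config$image_size),
                      tilt_axis_deg = config$tilt_axis_deg),
    images = lapply(seq_len(nrow(images)), function(i) {
      im <- list(file = images$file[i], tilt_deg = images$tilt_deg[i],
                 beam_center = c(images$center_x[i], images$center_y[i]))
      if (!is.na(images$beamstop_r[i])) {
        im$beamstop <- list(center = c(images$beamstop_x[i], images$beamstop_y[i]),
                            radius = images$beamstop_r[i])
      }
      im
    }))
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Read a tilt series of single-frame grayscale TIFF stills
#'
#' @param image_paths Character vector of TIFF paths.
#' @param metadata_path Path to the dataset YAML config (see
#'   [read_dataset_config()]); images are matched to metadata rows by file
#'   name (basename).
#' @param config Optional [instrument_config()] overriding the one in the
#'   metadata file.
#'
#' @return List of [tilt_image()] objects sorted by ascending tilt angle;
#'   pixel values are preserved losslessly as integers.
#' @export
read_tilt_series <- function(image_paths, metadata_path, config = NULL) {
  missing <- image_paths[!file.exists(image_paths)]
  if (length(missing)) stop("image file not found: ", missing[1])
  meta <- read_dataset_config(metadata_path)
  if (is.null(config)) config <- meta$config
  md <- meta$images
  if (nrow(md) != length(image_paths)) {
    stop("metadata lists ", nrow(md), " images but ", length(image_paths),
         " image paths were given")
  }
  imgs <- lapply(image_paths, function(p) {
    row <- match(basename(p), basename(md$file))
    if (is.na(row)) stop("no metadata entry for image: ", basename(p))
    px <- read_tiff_counts(p)
    bs <- NULL
    if (!is.na(md$beamstop_r[row])) {
      bs <- list(center = c(md$beamstop_x[row], md$beamstop_y[row]),
                 radius = md$beamstop_r[row])
    }
    tilt_image(px, md$tilt_deg[row],
               c(md$center_x[row], md$center_y[row]),
               beamstop = bs, id = basename(p))
  })
  imgs[order(vapply(imgs, function(im) im$tilt_deg, numeric(1)))]
}

#' Read a single-frame grayscale TIFF as an integer count matrix
#'
#' @param path TIFF path (8- or 16-bit grayscale, one frame).
#' @return Integer matrix indexed `[y + 1, x + 1]`.
#' @export
read_tiff_counts <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  r <- tiff::readTIFF(path, as.is = TRUE, all = TRUE)
  if (length(r) != 1L) {
    stop("expected a single-frame TIFF, got ", length(r), " frames: ", path)
  }
  m <- r[[1]]
  if (length(dim(m)) == 3L) {
    stop("expected a grayscale TIFF, got ", dim(m)[3], " channels (RGB?): ",
         path)
  }
  storage.mode(m) <- "integer"
  m
}

#' Write an integer count matrix as a 16-bit grayscale TIFF
#'
#' @param pixels Matrix of counts in \[0, 65535\]; values are clamped.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tiff_counts <- function(pixels, path) {
  m <- pmin(pmax(round(pixels), 0), 65535)
  tiff::writeTIFF(m / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' Read a spot-pick file
#'
#' One picked spot per line, whitespace-delimited: `x y role`, with role one
#' of `pick`, `friedel`, `reference` or `beamstop_center`. Friedel picks pair
#' up in file order (lines 1+2 form the first pair, etc.).
#'
#' @param path Path to the pick file.
#' @return A `spot_list`: data frame with columns `x`, `y`, `role`, plus
#'   attributes `friedel_pairs` (list of 2x2 matrices) and `reference`
#'   (2 x 2 matrix of the two reference picks, or NULL).
#' @export
read_spot_picks <- function(path) {
  if (!file.exists(path)) stop("spot-pick file not found: ", path)
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  roles <- c("pick", "friedel", "reference", "beamstop_center")
  rows <- lapply(keep, function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 3L) {
      stop("line ", i, ": expected 'x y role', got: ", lines[i])
    }
    xy <- suppressWarnings(as.numeric(f[1:2]))
    if (anyNA(xy)) stop("line ", i, ": non-numeric coordinates: ", lines[i])
    if (!(f[3] %in% roles)) {
      stop("line ", i, ": unknown role '", f[3], "' (expected ",
           paste(roles, collapse = "/"), ")")
    }
    data.frame(x = xy[1], y = xy[2], role = f[3], stringsAsFactors = FALSE)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(x = numeric(), y = numeric(), role = character())
  as_spot_list(df)
}

as_spot_list <- function(df) {
  nref <- sum(df$role == "reference")
  if (!(nref %in% c(0L, 2L))) {
    stop("a spot list must carry exactly 0 or 2 reference spots, found ", nref)
  }
  nfr <- sum(df$role == "friedel")
  if (nfr %% 2L != 0L) {
    stop("friedel picks must come in pairs, found ", nfr)
  }
  ref <- NULL
  if (nref == 2L) {
    ref <- as.matrix(df[df$role == "reference", c("x", "y")])
    if (all(ref[1, ] == ref[2, ])) stop("the two reference spots must be distinct")
  }
  fr <- df[df$role == "friedel", c("x", "y")]
  pairs <- if (nfr > 0) {
    lapply(seq_len(nfr / 2L), function(k) as.matrix(fr[(2 * k - 1):(2 * k), ]))
  } else list()
  structure(df, friedel_pairs = pairs, reference = ref,
            class = c("spot_list", "data.frame"))
}

#' Write a spot-pick file
#'
#' @param spots Data frame with columns `x`, `y`, `role`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spot_picks <- function(spots, path) {
  writeLines(sprintf("%.3f %.3f %s", spots$x, spots$y, spots$role), path)
  invisible(path)
}

#' Write a merged reflection file
#'
#' Emits one whitespace-delimited line per unique Miller index with columns
#' `h k l I F SigI SigF` in fixed decimal format, the free-format layout
#' downstream conversion tools accept.
#'
#' @param reflections Data frame with columns `h`, `k`, `l`, `I`, `F`, `SigI`,
#'   `SigF` (as produced by [merge_maxonly()] / [merge_threshold()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reflections <- function(reflections, path) {
  req <- c("h", "k", "l", "I", "F", "SigI", "SigF")
  if (!all(req %in% names(reflections))) {
    stop("reflections must have columns ", paste(req, collapse = " "))
  }
  key <- paste(reflections$h, reflections$k, reflections$l)
  if (anyDuplicated(key)) {
    stop("duplicate Miller index in reflection list (merge before writing): ",
         key[duplicated(key)][1])
  }
  lines <- sprintf("%d %d %d %.2f %.2f %.2f %.2f",
                   as.integer(reflections$h), as.integer(reflections$k),
                   as.integer(reflections$l), reflections$I, reflections$F,
                   reflections$SigI, reflections$SigF)
  writeLines(lines, path)
  invisible(path)
}

#' Read a reflection file written by [write_reflections()]
#'
#' @param path Path to the reflection text file.
#' @return Data frame with columns `h k l I F SigI SigF`.
#' @export
read_reflections <- function(path) {
  if (!file.exists(path)) stop("reflection file not found: ", path)
  df <- utils::read.table(path, col.names = c("h", "k", "l", "I", "F",
                                              "SigI", "SigF"))
  df$h <- as.integer(df$h); df$k <- as.integer(df$k); df$l <- as.integer(df$l)
  df
}
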