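#' Measure the background-subtracted intensity of one spot
#'
#' At the final indexing the predicted positions are used as-is (no mass
#' centering, so a spot cannot walk to a neighbouring Miller index). The
#' mean background from the box-minus-circle region is subtracted from every
#' pixel inside the circle and the remainder summed. The measurement is
#' recorded only when the contrast ratio clears the (deliberately low)
#' measurement threshold.
#'
#' @param pixels Image pixel matrix.
#' @param center `c(x, y)` predicted spot position, 0-based px.
#' @param box Box edge in px (default 10).
#' @param threshold Minimum contrast ratio to record (default 0.005).
#' @return List `recorded` (logical), `I` (background-subtracted sum, NA when
#'   the box is off raster), `ratio`, `measurement` (the `box_measurement`),
#'   `reason` (`"ok"`, `"off_raster"`, `"low_contrast"`).
#' @export
measure_intensity <- function(pixels, center, box = 10, threshold = 0.005) {
  m <- box_measurement(pixels, center, box)
  if (is.null(m)) {
    return(list(recorded = FALSE, I = NA_real_, ratio = NA_real_,
                measurement = NULL, reason = "off_raster"))
  }
  I <- m$circle_sum - m$n_circle * m$background_mean
  if (m$ratio < threshold) {
    return(list(recorded = FALSE, I = I, ratio = m$ratio, measurement = m,
                reason = "low_contrast"))
  }
  list(recorded = TRUE, I = I, ratio = m$ratio, measurement = m,
       reason = "ok")
}

#' Measure intensities for all final predictions on an image
#'
#' @param image A [tilt_image()].
#' @param predictions An `indexing_result` for this image (final indexing,
#'   not mass centered).
#' @param box Box edge in px.
#' @param threshold Measurement contrast threshold (default 0.005).
#' @return Data frame `h k l image_id I ratio x y` of recorded measurements.
#' @export
measure_intensities <- function(image, predictions, box = 10,
                                threshold = 0.005) {
  rows <- list()
  for (i in seq_len(nrow(predictions))) {
    p <- predictions[i, ]
    if (!p$in_bounds || p$masked) next
    m <- measure_intensity(image$pixels, c(p$x, p$y), box, threshold)
    if (!m$recorded) next
    rows[[length(rows) + 1L]] <- data.frame(h = p$h, k = p$k, l = p$l,
                                            image_id = image$id, I = m$I,
                                            ratio = m$ratio, x = p$x, y = p$y,
                                            stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(h = integer(), k = integer(), l = integer(),
               image_id = character(), I = numeric(), ratio = numeric(),
               x = numeric(), y = numeric())
}

# The 8 rotations of point group 422 as h,k,l maps.
p422_ops <- function() {
  list(function(h) h,
       function(h) c(-h[1], -h[2], h[3]),
       function(h) c(-h[2], h[1], h[3]),
       function(h) c(h[2], -h[1], h[3]),
       function(h) c(-h[1], h[2], -h[3]),
       function(h) c(h[1], -h[2], -h[3]),
       function(h) c(h[2], h[1], -h[3]),
       function(h) c(-h[2], -h[1], -h[3]))
}

#' Symmetry orbit of a Miller index under Laue group 4/mmm
#'
#' The 8 rotations of point group 422 plus the Friedel inversion give 16
#' operations; the orbit is the distinct set of images of `hkl` under them.
#'
#' @param hkl Integer Miller triple.
#' @return Integer matrix, one distinct equivalent per row (1 to 16 rows).
#' @export
p422_orbit <- function(hkl) {
  hkl <- as.integer(hkl)
  stopifnot(length(hkl) == 3L)
  eq <- lapply(p422_ops(), function(f) f(hkl))
  eq <- c(eq, lapply(eq, function(h) -h))
  m <- unique(do.call(rbind, eq))
  storage.mode(m) <- "integer"
  dimnames(m) <- list(NULL, c("h", "k", "l"))
  m
}

#' Canonical asymmetric-unit representative under 4/mmm
#'
#' The representative is the lexicographically greatest orbit member with
#' h >= k >= 0 and l >= 0 when one exists, else the lexicographic maximum —
#' a fixed, deterministic choice so every orbit maps to exactly one key.
#'
#' @param hkl Integer Miller triple.
#' @return Integer triple.
#' @export
canonical_hkl_p422 <- function(hkl) {
  orb <- p422_orbit(hkl)
  lexmax <- function(m) {
    m[order(m[, 1], m[, 2], m[, 3], decreasing = TRUE)[1], ]
  }
  asu <- orb[orb[, 1] >= orb[, 2] & orb[, 2] >= 0 & orb[, 3] >= 0, ,
             drop = FALSE]
  if (nrow(asu)) lexmax(asu) else lexmax(orb)
}

# Group measurements by canonical 4/mmm index; returns list of data frames.
split_by_orbit <- function(measurements) {
  key <- vapply(seq_len(nrow(measurements)), function(i) {
    paste(canonical_hkl_p422(c(measurements$h[i], measurements$k[i],
                               measurements$l[i])), collapse = " ")
  }, character(1))
  split(measurements, key)
}

reflection_row <- function(hkl, I, SigI, n) {
  Ipos <- max(I, 0)  # clamp before sqrt; raw I kept in the I column? no: I as merged
  Fv <- sqrt(Ipos)
  SigF <- if (n >= 2L && Fv > 0) SigI / (2 * Fv) else sqrt(Fv)
  data.frame(h = hkl[1], k = hkl[2], l = hkl[3], I = I, F = Fv,
             SigI = SigI, SigF = SigF, n = n)
}

#' Merge symmetry-equivalent measurements keeping only the maximum
#'
#' In still-diffraction tilt series most measurements are partial; the
#' largest recorded intensity in each 4/mmm orbit is taken to best represent
#' the complete reflection and all smaller measurements are discarded. With
#' a single surviving observation per index, Rmerge cannot be computed, and
#' SigI/SigF are estimated as sqrt(I) and sqrt(F).
#'
#' @param measurements Data frame with columns `h`, `k`, `l`, `I` (one row
#'   per recorded measurement).
#' @return Data frame of merged reflections, one row per canonical index:
#'   `h k l I F SigI SigF n` (`n` = measurements seen in the orbit), sorted
#'   by h, k, l.
#' @export
merge_maxonly <- function(measurements) {
  orbits <- split_by_orbit(measurements)
  out <- lapply(names(orbits), function(key) {
    hkl <- as.integer(strsplit(key, " ")[[1]])
    I <- max(orbits[[key]]$I)
    r <- reflection_row(hkl, I, SigI = sqrt(max(I, 0)),
                        n = nrow(orbits[[key]]))
    r$SigF <- sqrt(r$F)
    r
  })
  df <- do.call(rbind, out)
  if (is.null(df)) return(empty_reflections())
  df[order(df$h, df$k, df$l), , drop = FALSE]
}

empty_reflections <- function() {
  data.frame(h = integer(), k = integer(), l = integer(), I = numeric(),
             F = numeric(), SigI = numeric(), SigF = numeric(), n = integer())
}

#' Merge symmetry-equivalent measurements above a fractional cutoff
#'
#' Within each 4/mmm orbit, only measurements with I >= cutoff x I_max are
#' kept (cutoff 1.0 therefore reproduces max-only merging); the merged
#' intensity is the mean of the kept measurements. SigI is the sample
#' standard deviation when two or more measurements survive, else sqrt(I).
#' Rmerge = sum |I_i - <I>| / sum I_i over all kept measurements.
#'
#' @param measurements Data frame with columns `h`, `k`, `l`, `I`.
#' @param cutoff Fraction of the orbit maximum, in (0, 1].
#' @return List `reflections` (data frame `h k l I F SigI SigF n`, `n` =
#'   kept measurements) and `rmerge` (NA when no orbit keeps >= 2).
#' @export
merge_threshold <- function(measurements, cutoff) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0 ||
      cutoff > 1) {
    stop("cutoff must be a fraction in (0, 1]")
  }
  orbits <- split_by_orbit(measurements)
  out <- lapply(names(orbits), function(key) {
    hkl <- as.integer(strsplit(key, " ")[[1]])
    I <- orbits[[key]]$I
    kept <- I[I >= cutoff * max(I)]
    n <- length(kept)
    Im <- mean(kept)
    SigI <- if (n >= 2L) stats::sd(kept) else sqrt(max(Im, 0))
    reflection_row(hkl, Im, SigI, n)
  })
  # Rmerge over all kept measurements; orbits with one survivor add zero to
  # the numerator but their intensity to the denominator
  num <- 0; den <- 0; any_multi <- FALSE
  for (key in names(orbits)) {
    I <- orbits[[key]]$I
    kept <- I[I >= cutoff * max(I)]
    if (length(kept) >= 2L) any_multi <- TRUE
    num <- num + sum(abs(kept - mean(kept)))
    den <- den + sum(kept)
  }
  df <- do.call(rbind, out)
  df <- if (is.null(df)) empty_reflections() else
    df[order(df$h, df$k, df$l), , drop = FALSE]
  rmerge <- if (any_multi && den > 0) num / den else NA_real_
  list(reflections = df, rmerge = rmerge)
}

#' Merge statistics across cutoffs
#'
#' @param measurements Data frame with columns `h`, `k`, `l`, `I`.
#' @param cutoffs Numeric vector of fractional cutoffs in (0, 1].
#' @return Data frame `cutoff`, `rmerge`, `n_reflections`, `n_kept`
#'   (total kept measurements), `mean_multiplicity`.
#' @export
merge_statistics <- function(measurements, cutoffs = c(0.1, 0.25, 0.5, 0.75,
                                                       0.9, 1.0)) {
  do.call(rbind, lapply(cutoffs, function(cf) {
    m <- merge_threshold(measurements, cf)
    data.frame(cutoff = cf, rmerge = m$rmerge,
               n_reflections = nrow(m$reflections),
               n_kept = sum(m$reflections$n),
               mean_multiplicity = mean(m$reflections$n))
  }))
}
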