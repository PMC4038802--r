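#' Miller indices of the two reference spots of an image
#'
#' The references are user-chosen bright reflections believed to be exactly
#' bisected by the Ewald sphere. Their reconstructed reciprocal vectors are
#' multiplied by the inverse unit-cell matrix and rounded to the nearest
#' integers; the rounding residual is reported as a quality metric.
#'
#' @param ref_xy 2 x 2 matrix of the two reference spot positions (px).
#' @param basis 3 x 3 unit-cell matrix (rows a*, b*, c*, px).
#' @param image A [tilt_image()].
#' @param config An [instrument_config()].
#' @param residual_limit Warn when any fractional-index component deviates
#'   from an integer by more than this (default 0.3).
#' @return List `hkl` (2 x 3 integer matrix), `residual` (2 x 3 matrix of
#'   absolute rounding residuals).
#' @export
index_reference_spots <- function(ref_xy, basis, image, config,
                                  residual_limit = 0.3) {
  ref_xy <- rbind_xy(ref_xy)
  stopifnot(nrow(ref_xy) == 2L)
  v <- spot_to_v(ref_xy, image, config)
  frac <- v %*% solve(basis)   # v = hkl %*% basis  =>  hkl = v %*% basis^-1
  hkl <- round(frac)
  res <- abs(frac - hkl)
  for (i in 1:2) {
    if (any(res[i, ] > residual_limit)) {
      warning(sprintf(paste0("reference spot %d on image %s indexes poorly: ",
                             "fractional hkl (%.2f, %.2f, %.2f); suspect a bad ",
                             "reference pick or unit-cell vectors"),
                      i, image$id, frac[i, 1], frac[i, 2], frac[i, 3]))
    }
  }
  storage.mode(hkl) <- "integer"
  dimnames(hkl) <- list(NULL, c("h", "k", "l"))
  list(hkl = hkl, residual = res)
}

#' Check vector normal to the plane of the two reference reflections
#'
#' @param hkl1,hkl2 Integer Miller triples of the two reference spots.
#' @return Integer triple `q = hkl1 x hkl2`; the dot product hkl . q tests
#'   whether a Miller index lies in the reference plane.
#' @export
compute_check_vector <- function(hkl1, hkl2) {
  stopifnot(length(hkl1) == 3L, length(hkl2) == 3L)
  q <- c(hkl1[2] * hkl2[3] - hkl1[3] * hkl2[2],
         hkl1[3] * hkl2[1] - hkl1[1] * hkl2[3],
         hkl1[1] * hkl2[2] - hkl1[2] * hkl2[1])
  if (all(q == 0)) stop("reference Miller indices are collinear; ",
                        "the reference plane is undefined")
  as.integer(q)
}

#' Predict the reflections visible on a still pattern
#'
#' Enumerates Miller indices within the resolution limit whose normalized
#' dot product with the check vector is at most the Laue-zone threshold L,
#' i.e. |hkl . q| / |q| <= L, and projects them onto the detector at the
#' image's tilt. Raising L widens the predicted Laue zones, trading more
#' captured reflections against more partial intensities and false
#' positives.
#'
#' @param basis 3 x 3 unit-cell matrix (px).
#' @param q Integer check vector from [compute_check_vector()].
#' @param L Laue-zone threshold in reciprocal-lattice plane-spacing units
#'   (default 0.15).
#' @param image A [tilt_image()].
#' @param config An [instrument_config()].
#' @param resolution_limit High-resolution cutoff in Å.
#' @return An `indexing_result`: data frame with columns `h`, `k`, `l`,
#'   `x`, `y` (0-based detector px, beam center added), `r_px`, `zone`
#'   (hkl.q/|q|), `in_bounds`, `masked`; attributes `q`, `L`, `image_id`,
#'   `tilt_deg`. Predictions under the beamstop are flagged, not dropped.
#' @export
predict_spots <- function(basis, q, L = 0.15, image, config,
                          resolution_limit) {
  stopifnot(L > 0)
  r_max <- radius_at_resolution(resolution_limit, config)
  nrm <- sqrt(rowSums(basis^2))
  hmax <- ceiling(r_max / nrm)
  grid <- expand.grid(h = -hmax[1]:hmax[1], k = -hmax[2]:hmax[2],
                      l = -hmax[3]:hmax[3])
  hkl <- as.matrix(grid)
  zone <- as.numeric(hkl %*% q) / sqrt(sum(q^2))
  keep <- abs(zone) <= L
  hkl <- hkl[keep, , drop = FALSE]; zone <- zone[keep]
  v <- hkl %*% basis
  r3 <- sqrt(rowSums(v^2))
  keep <- r3 <= r_max & r3 > 0
  hkl <- hkl[keep, , drop = FALSE]; zone <- zone[keep]; v <- v[keep, , drop = FALSE]
  if (nrow(hkl) == 0L) {
    warning("no spots predicted on image ", image$id,
            "; check the reference spots and the Laue threshold")
  }
  xy <- project_to_detector(v, image$tilt_deg, config)
  x <- xy[, 1] + image$beam_center[1]
  y <- xy[, 2] + image$beam_center[2]
  nx <- ncol(image$pixels); ny <- nrow(image$pixels)
  in_bounds <- x >= 0 & x <= nx - 1 & y >= 0 & y <= ny - 1
  masked <- under_beamstop(cbind(x, y), image)
  out <- data.frame(h = as.integer(hkl[, 1]), k = as.integer(hkl[, 2]),
                    l = as.integer(hkl[, 3]), x = x, y = y,
                    r_px = sqrt(xy[, 1]^2 + xy[, 2]^2), zone = zone,
                    in_bounds = in_bounds, masked = masked)
  structure(out, q = q, L = L, image_id = image$id, tilt_deg = image$tilt_deg,
            class = c("indexing_result", "data.frame"))
}

#' Index one image end to end
#'
#' Convenience wrapper: index the two reference spots, build the check
#' vector, and predict all spots on the image.
#'
#' @inheritParams predict_spots
#' @param ref_xy 2 x 2 matrix of reference spot positions (px).
#' @return An `indexing_result` (see [predict_spots()]); its `ref_hkl`
#'   attribute carries the reference Miller indices.
#' @export
index_image <- function(ref_xy, basis, image, config, L = 0.15,
                        resolution_limit) {
  refs <- index_reference_spots(ref_xy, basis, image, config)
  q <- compute_check_vector(refs$hkl[1, ], refs$hkl[2, ])
  pred <- predict_spots(basis, q, L, image, config, resolution_limit)
  attr(pred, "ref_hkl") <- refs$hkl
  attr(pred, "ref_residual") <- refs$residual
  pred
}
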