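#' Rotation matrix for a goniometer tilt
#'
#' Right-handed rotation by `theta_deg` about the in-plane tilt axis, whose
#' direction on the detector is `axis_deg` from the +x axis (default: the
#' image y axis). Applied to centered detector coordinates it carries a spot
#' observed at tilt θ into the laboratory (untilted) reciprocal frame.
#'
#' @param theta_deg Tilt angle in degrees.
#' @param axis_deg In-plane axis angle in degrees from +x (default 90).
#' @return 3 x 3 rotation matrix.
#' @export
tilt_rotation <- function(theta_deg, axis_deg = 90) {
  th <- theta_deg * pi / 180
  u <- c(cos(axis_deg * pi / 180), sin(axis_deg * pi / 180), 0)
  ct <- cos(th); st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  # Rodrigues form for a unit axis in the detector plane
  matrix(c(ct + ux^2 * (1 - ct), ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
           uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct), uy * uz * (1 - ct) - ux * st,
           uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)),
         nrow = 3, byrow = TRUE)
}

#' Ewald-sphere curvature correction (sagitta) at a detector radius
#'
#' The reciprocal-space depth, in pixels, of the Ewald sphere below the
#' tangent detector plane at in-plane radius r from the beam center. The
#' sphere has radius 1/λ (Å⁻¹), i.e. `c/λ` pixels; the exact sagitta is
#' `c · [(1/λ) − sqrt((1/λ)² − (r/c)²)]`. A small-angle form `λ r² / (2c)`
#' is available for comparison. Positive z points from the detector plane
#' toward the sphere center (upstream along the beam).
#'
#' @param xy_centered `c(dx, dy)` offset from the beam center in px, or an
#'   n x 2 matrix of offsets.
#' @param config An [instrument_config()].
#' @param form `"exact"` (default) or `"small_angle"`.
#' @return Numeric vector of depths in px; 0 at r = 0.
#' @export
ewald_z <- function(xy_centered, config, form = c("exact", "small_angle")) {
  form <- match.arg(form)
  xy <- rbind_xy(xy_centered)
  r2 <- xy[, 1]^2 + xy[, 2]^2
  R <- config$px_per_inv_angstrom / config$wavelength  # Ewald radius in px
  if (any(r2 >= R^2)) {
    stop("offset radius ", sqrt(max(r2)), " px is at or beyond the Ewald ",
         "sphere equator (", R, " px)")
  }
  switch(form,
         exact = R - sqrt(R^2 - r2),
         small_angle = r2 / (2 * R))
}

#' Reconstruct the 3D reciprocal-space vector of a picked spot
#'
#' Lifts centered detector coordinates onto the Ewald sphere (the sagitta
#' gives the out-of-plane component; the in-plane displacement due to the
#' curvature is negligible at these wavelengths and is ignored) and rotates
#' by the image's tilt angle into the laboratory frame.
#'
#' @param xy Spot position(s) in 0-based detector px: `c(x, y)` or n x 2.
#' @param image A [tilt_image()] supplying tilt angle and beam center.
#' @param config An [instrument_config()].
#' @return n x 3 matrix of reciprocal vectors in px (laboratory frame).
#' @export
spot_to_v <- function(xy, image, config) {
  xy <- rbind_xy(xy)
  d <- cbind(xy[, 1] - image$beam_center[1], xy[, 2] - image$beam_center[2])
  z <- ewald_z(d, config)
  R <- tilt_rotation(image$tilt_deg, config$tilt_axis_deg)
  v <- cbind(d[, 1], d[, 2], z) %*% t(R)
  dimnames(v) <- list(NULL, c("vx", "vy", "vz"))
  v
}

#' Project laboratory-frame reciprocal vectors onto a tilted detector
#'
#' Applies the inverse tilt rotation and drops the out-of-plane component:
#' the inverse of [spot_to_v()] up to the Ewald residual. Add the image's
#' beam center to obtain drawable detector coordinates.
#'
#' @param v n x 3 matrix (or length-3 vector) of reciprocal vectors, px.
#' @param tilt_deg Tilt angle of the target image in degrees.
#' @param config An [instrument_config()].
#' @return n x 2 matrix of centered in-plane offsets `(x', y')` in px.
#' @export
project_to_detector <- function(v, tilt_deg, config) {
  if (!is.matrix(v)) v <- matrix(v, ncol = 3L)
  R <- tilt_rotation(tilt_deg, config$tilt_axis_deg)
  w <- v %*% R  # v %*% R == t(t(R) %*% t(v)) = R(-theta) applied to rows
  out <- w[, 1:2, drop = FALSE]
  dimnames(out) <- list(NULL, c("x", "y"))
  out
}

#' Out-of-plane residual of reciprocal vectors on a tilted image
#'
#' Signed distance (px) between a vector's out-of-plane component in the
#' image frame and the Ewald sagitta at its in-plane radius: zero for a
#' reflection exactly bisected by the sphere.
#'
#' @inheritParams project_to_detector
#' @return Numeric vector of residuals in px.
#' @export
ewald_residual <- function(v, tilt_deg, config) {
  if (!is.matrix(v)) v <- matrix(v, ncol = 3L)
  R <- tilt_rotation(tilt_deg, config$tilt_axis_deg)
  w <- v %*% R
  r2 <- w[, 1]^2 + w[, 2]^2
  RE <- config$px_per_inv_angstrom / config$wavelength
  sag <- ifelse(r2 < RE^2, RE - sqrt(pmax(RE^2 - r2, 0)), NA_real_)
  w[, 3] - sag
}

#' Beam center from user-picked Friedel pairs
#'
#' Friedel mates hkl and -h-k-l are symmetric about the beam center on a
#' pattern, so each pair's midpoint estimates the center; the estimate is the
#' mean of midpoints over all pairs.
#'
#' @param pairs List of 2 x 2 matrices (rows = the two mates, columns x, y),
#'   or a single 2 x 2 matrix.
#' @return `c(x, y)` beam center in px.
#' @export
beam_center_from_friedel <- function(pairs) {
  if (is.matrix(pairs)) pairs <- list(pairs)
  if (length(pairs) == 0L) stop("at least one Friedel pair is required")
  mids <- vapply(pairs, function(p) {
    p <- rbind_xy(p)
    if (nrow(p) != 2L) stop("each Friedel pair must be two points")
    if (all(p[1, ] == p[2, ])) {
      stop("degenerate Friedel pair: the two picks coincide")
    }
    colMeans(p)
  }, numeric(2))
  rowMeans(mids)
}
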