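# Integer window of a box of edge `box` centered at 0-based pixel coordinate
# ctr = c(x, y). Returns NULL when it does not fit in the raster.
box_window <- function(pixels, ctr, box) {
  h <- floor(box / 2)
  cx <- round(ctr[1]); cy <- round(ctr[2])
  x0 <- cx - h; x1 <- cx + h; y0 <- cy - h; y1 <- cy + h
  if (x0 < 0 || y0 < 0 || x1 > ncol(pixels) - 1 || y1 > nrow(pixels) - 1) {
    return(NULL)
  }
  list(m = pixels[(y0:y1) + 1L, (x0:x1) + 1L, drop = FALSE],
       x = x0:x1, y = y0:y1)
}

#' Refine a spot position by mass centering
#'
#' Draws a square box around the predicted position, sums each row and
#' column of the enclosed pixel block, and moves the center to the column
#' and row of maximum sum (ties break to the lowest index). The process is
#' run twice; if the second pass moves the center by more than `max_shift`
#' pixels in either direction the spot is discarded, which prevents a
#' prediction from walking to an adjacent Miller index.
#'
#' @param pixels Image pixel matrix (`[y + 1, x + 1]` indexing).
#' @param start `c(x, y)` predicted position, 0-based px.
#' @param box Box edge length in px (default 10).
#' @param max_shift Maximum tolerated second-pass shift in px (default 2).
#' @return List `center` (`c(x, y)` or NULL), `kept` (logical), `reason`
#'   (`"ok"`, `"off_raster"` or `"walked"`), `shift2` (second-pass shift).
#' @export
mass_center <- function(pixels, start, box = 10, max_shift = 2) {
  # argmax with ties resolved toward the current center (then lowest index),
  # so a featureless box is a fixed point of the pass
  argmax_near <- function(sums, pos, ctr) {
    cand <- pos[sums == max(sums)]
    cand[order(abs(cand - ctr), cand)][1]
  }
  pass <- function(ctr) {
    w <- box_window(pixels, ctr, box)
    if (is.null(w)) return(NULL)
    c(argmax_near(colSums(w$m), w$x, ctr[1]),
      argmax_near(rowSums(w$m), w$y, ctr[2]))
  }
  c1 <- pass(start)
  if (is.null(c1)) {
    return(list(center = NULL, kept = FALSE, reason = "off_raster",
                shift2 = NA_real_))
  }
  c2 <- pass(c1)
  if (is.null(c2)) {
    return(list(center = NULL, kept = FALSE, reason = "off_raster",
                shift2 = NA_real_))
  }
  shift2 <- max(abs(c2 - c1))
  if (shift2 > max_shift) {
    return(list(center = NULL, kept = FALSE, reason = "walked",
                shift2 = shift2))
  }
  list(center = as.numeric(c2), kept = TRUE, reason = "ok", shift2 = shift2)
}

#' Measure a spot's contrast against its local background
#'
#' A square box and its inscribed circle (diameter = box edge) are centered
#' on the spot. Background is the mean pixel intensity inside the square but
#' outside the circle; the contrast ratio is
#' `(mean inside circle - background) / background`.
#'
#' @inheritParams mass_center
#' @param center `c(x, y)` spot center, 0-based px.
#' @return A `box_measurement`: list with `center`, `box`, `circle_mean`,
#'   `background_mean`, `ratio`, `circle_sum`, `n_circle`, `n_background`,
#'   `flag` (`""` or `"zero_background"`), or NULL when the box is off
#'   raster.
#' @export
box_measurement <- function(pixels, center, box = 10) {
  w <- box_window(pixels, center, box)
  if (is.null(w)) return(NULL)
  gx <- matrix(w$x, nrow = length(w$y), ncol = length(w$x), byrow = TRUE)
  gy <- matrix(w$y, nrow = length(w$y), ncol = length(w$x))
  incirc <- (gx - round(center[1]))^2 + (gy - round(center[2]))^2 <= (box / 2)^2
  n_in <- sum(incirc); n_bg <- sum(!incirc)
  if (n_bg == 0L) stop("box too small: no background pixels outside the circle")
  cmean <- mean(w$m[incirc])
  bmean <- mean(w$m[!incirc])
  flag <- ""
  ratio <- if (bmean > 0) (cmean - bmean) / bmean else {
    flag <- "zero_background"
    if (cmean > 0) Inf else 0
  }
  structure(list(center = as.numeric(center), box = box, circle_mean = cmean,
                 background_mean = bmean, ratio = ratio,
                 circle_sum = sum(w$m[incirc]), n_circle = n_in,
                 n_background = n_bg, flag = flag),
            class = "box_measurement")
}

#' Keep or discard a spot by its spot-to-background contrast
#'
#' @inheritParams box_measurement
#' @param threshold Minimum contrast ratio to keep (boundary inclusive).
#'   Around 0.10 for refinement, where only clean complete reflections are
#'   wanted; much lower (~0.005) at intensity measurement, to capture weak
#'   spots.
#' @return List `keep` (logical), `measurement` (a `box_measurement`, or
#'   NULL when the box is off raster — then `keep` is FALSE).
#' @export
contrast_filter <- function(pixels, center, box = 10, threshold = 0.10) {
  m <- box_measurement(pixels, center, box)
  if (is.null(m)) return(list(keep = FALSE, measurement = NULL))
  list(keep = m$ratio >= threshold, measurement = m)
}

#' Refine all predicted spots of one image
#'
#' Mass-centers every in-bounds, unmasked prediction and applies the
#' contrast filter, returning the surviving refined positions.
#'
#' @param image A [tilt_image()].
#' @param predictions An `indexing_result` from [predict_spots()].
#' @param box Box edge (px).
#' @param max_shift Mass-centering walk limit (px).
#' @param threshold Contrast threshold (default 0.10).
#' @return Data frame `h k l x y ratio` of kept refined spots, with
#'   attribute `counts` = named vector of discard tallies.
#' @export
refine_spots <- function(image, predictions, box = 10, max_shift = 2,
                         threshold = 0.10) {
  counts <- c(kept = 0L, off_raster = 0L, walked = 0L, low_contrast = 0L,
              masked = 0L)
  rows <- list()
  for (i in seq_len(nrow(predictions))) {
    p <- predictions[i, ]
    if (!p$in_bounds || p$masked) {
      counts["masked"] <- counts["masked"] + 1L
      next
    }
    mc <- mass_center(image$pixels, c(p$x, p$y), box, max_shift)
    if (!mc$kept) {
      counts[mc$reason] <- counts[mc$reason] + 1L
      next
    }
    cf <- contrast_filter(image$pixels, mc$center, box, threshold)
    if (!cf$keep) {
      counts["low_contrast"] <- counts["low_contrast"] + 1L
      next
    }
    counts["kept"] <- counts["kept"] + 1L
    rows[[length(rows) + 1L]] <- data.frame(h = p$h, k = p$k, l = p$l,
                                            x = mc$center[1], y = mc$center[2],
                                            ratio = cf$measurement$ratio)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(h = integer(), k = integer(), l = integer(),
               x = numeric(), y = numeric(), ratio = numeric())
  attr(out, "counts") <- counts
  out
}

# Match rows of `basis` to rows of `previous` (sign-agnostic) and return the
# per-vector angle (deg) and relative norm deltas plus the relabelled basis.
match_basis <- function(basis, previous) {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  best <- NULL
  for (pm in perms) {
    b <- basis[pm, , drop = FALSE]
    ang <- vapply(1:3, function(i) vec_angle_folded(b[i, ], previous[i, ]),
                  numeric(1))
    if (is.null(best) || sum(ang) < best$total) {
      best <- list(perm = pm, b = b, ang = ang, total = sum(ang))
    }
  }
  b <- best$b
  for (i in 1:3) if (sum(b[i, ] * previous[i, ]) < 0) b[i, ] <- -b[i, ]
  nrm_new <- sqrt(rowSums(b^2)); nrm_old <- sqrt(rowSums(previous^2))
  rownames(b) <- c("a*", "b*", "c*")
  list(basis = b, angle_delta = best$ang,
       norm_delta = abs(nrm_new - nrm_old) / nrm_old)
}

#' Recalculate unit-cell vectors from a refined spot set
#'
#' Reruns the difference-vector / length-filter / angular-grouping pipeline
#' on the (larger, mass-centered) refined spot set, using the previous basis
#' as the length and angle target, and reports how far the basis moved.
#'
#' When `polish = TRUE` (the default) the grouped basis is then refined by
#' index-constrained least squares: every refined spot is assigned the
#' nearest integer Miller index under the grouped basis, clean assignments
#' are kept, and the basis is refit to minimize the summed squared residual
#' |v - hkl B|^2. Averaged difference vectors are vulnerable to a selection
#' bias of still tilt series — a pair of reflections one reciprocal cell
#' apart is only co-observed at favourable tilts, which correlates their
#' Ewald offsets — while the least-squares fit uses each spot singly and is
#' immune to it.
#'
#' @param v n x 3 matrix of reciprocal vectors of all kept refined spots.
#' @param previous Previous 3 x 3 unit-cell matrix.
#' @param length_tol,angular_tol,angle_tol Passed to the grouping/selection
#'   steps (defaults 0.05, 8, 8).
#' @param polish Apply the least-squares polish (default TRUE).
#' @param polish_residual_limit Spots whose fractional index deviates from
#'   an integer by more than this (any component) are left out of the fit
#'   (default 0.3).
#' @return List `basis` (relabelled to match `previous`), `angle_delta`
#'   (deg, per vector), `norm_delta` (relative, per vector), `degenerate`
#'   (TRUE when the refined set could not produce a basis and `previous` was
#'   kept, with a warning).
#' @export
recalculate_vectors <- function(v, previous, length_tol = 0.05,
                                angular_tol = 8, angle_tol = 8,
                                polish = TRUE, polish_residual_limit = 0.3) {
  par_prev <- basis_parameters(previous)
  res <- tryCatch({
    d <- difference_vectors(v)
    f <- filter_by_length(d, par_prev$lengths, length_tol)
    g <- group_and_average(f, angular_tol, length_tol)
    select_cell_vectors(g, par_prev$lengths, par_prev$angles,
                        length_tol, angle_tol)
  }, error = function(e) e)
  if (inherits(res, "error")) {
    warning("refined spot set is degenerate (", conditionMessage(res),
            "); keeping the previous unit-cell vectors")
    return(list(basis = previous, angle_delta = rep(0, 3),
                norm_delta = rep(0, 3), degenerate = TRUE))
  }
  basis <- res$basis
  if (polish) {
    polished <- tryCatch({
      frac <- v %*% solve(basis)
      hkl <- round(frac)
      ok <- apply(abs(frac - hkl), 1L, max) <= polish_residual_limit
      H <- hkl[ok, , drop = FALSE]
      if (sum(ok) < 6L || qr(H)$rank < 3L) stop("not enough clean spots")
      solve(t(H) %*% H, t(H) %*% v[ok, , drop = FALSE])
    }, error = function(e) NULL)
    if (!is.null(polished)) basis <- polished
  }
  m <- match_basis(basis, previous)
  list(basis = m$basis, angle_delta = m$angle_delta,
       norm_delta = m$norm_delta, degenerate = FALSE)
}

#' Iteratively refine the unit-cell vectors against the whole tilt series
#'
#' One iteration: index every image with the current basis and its reference
#' spots, mass-center and contrast-filter the predictions, lift the kept
#' spots to reciprocal space, and recalculate the basis from them. Iteration
#' stops when the basis change falls below `angle_tol_deg` / `norm_tol` or
#' after `max_iter` rounds.
#'
#' @param images List of [tilt_image()]s.
#' @param ref_xy_list List of 2 x 2 reference-spot matrices, one per image.
#' @param basis Initial 3 x 3 unit-cell matrix.
#' @param config An [instrument_config()].
#' @param L Laue-zone threshold.
#' @param resolution_limit Å cutoff for prediction.
#' @param box,max_shift,threshold Refinement parameters (see
#'   [refine_spots()]).
#' @param angle_tol_deg,norm_tol Convergence tolerances (defaults 0.2 deg,
#'   0.005 relative).
#' @param max_iter Maximum iterations (default 10).
#' @return List `basis` (final), `iterations` (data frame with per-iteration
#'   max angle/norm deltas and kept-spot counts), `converged` (logical).
#' @export
refine_cell <- function(images, ref_xy_list, basis, config, L = 0.15,
                        resolution_limit, box = 10, max_shift = 2,
                        threshold = 0.10, angle_tol_deg = 0.2,
                        norm_tol = 0.005, max_iter = 10L) {
  hist <- list()
  seen <- list(basis)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    vs <- list()
    nkept <- 0L
    for (i in seq_along(images)) {
      pred <- index_image(ref_xy_list[[i]], basis, images[[i]], config, L,
                          resolution_limit)
      ref <- refine_spots(images[[i]], pred, box, max_shift, threshold)
      if (nrow(ref)) {
        vs[[length(vs) + 1L]] <- spot_to_v(as.matrix(ref[, c("x", "y")]),
                                           images[[i]], config)
        nkept <- nkept + nrow(ref)
      }
    }
    v <- do.call(rbind, vs)
    rec <- recalculate_vectors(v, basis)
    basis <- rec$basis
    hist[[it]] <- data.frame(iteration = it, n_spots = nkept,
                             max_angle_delta = max(rec$angle_delta),
                             max_norm_delta = max(rec$norm_delta),
                             degenerate = rec$degenerate)
    if (max(rec$angle_delta) <= angle_tol_deg &&
        max(rec$norm_delta) <= norm_tol) {
      converged <- TRUE
      break
    }
    # the update map is deterministic: revisiting an earlier basis means the
    # iteration has entered a cycle and will not improve further
    if (any(vapply(seen, function(b) max(abs(b - basis)) < 1e-9,
                   logical(1)))) {
      break
    }
    seen[[length(seen) + 1L]] <- basis
  }
  list(basis = basis, iterations = do.call(rbind, hist), converged = converged)
}
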