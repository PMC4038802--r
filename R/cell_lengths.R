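#' Pairwise distance distribution of reciprocal-space vectors
#'
#' For spots with adjacent Miller indices the pair distance equals a
#' unit-cell dimension, so unit-cell lengths appear as the small-distance
#' peaks of this distribution when a few hundred spots are picked across
#' several tilts.
#'
#' @param v n x 3 matrix of reciprocal vectors (px), n >= 2.
#' @param bin_width Histogram bin width in px (default 1).
#' @param min_prominence_frac Minimum peak prominence as a fraction of the
#'   tallest histogram bin (default 0.05).
#' @return An object of class `distance_distribution`: list with `distances`
#'   (sorted, length n(n-1)/2), `histogram` (data frame `mid`, `count`),
#'   `peaks` (data frame `position`, `height`, `prominence`, ascending by
#'   position) and `bin_width`.
#' @export
pairwise_distances <- function(v, bin_width = 1, min_prominence_frac = 0.05) {
  if (!is.matrix(v)) v <- matrix(v, ncol = 3L)
  if (nrow(v) < 2L) stop("at least 2 vectors are required")
  d <- sort(as.numeric(stats::dist(v)))
  breaks <- seq(0, max(d) + bin_width, by = bin_width)
  h <- graphics::hist(d, breaks = breaks, plot = FALSE)
  counts <- h$counts
  mids <- h$mids
  pk <- find_peaks(counts, min_prominence = min_prominence_frac * max(counts))
  peaks <- data.frame(position = mids[pk$index], height = pk$height,
                      prominence = pk$prominence)
  structure(list(distances = d,
                 histogram = data.frame(mid = mids, count = counts),
                 peaks = peaks, bin_width = bin_width),
            class = "distance_distribution")
}

# Local maxima of a non-negative series with a prominence floor.
# Prominence of a peak = height minus the higher of the two saddle minima
# encountered before reaching a strictly taller value on each side (series
# ends count as saddles). Plateau maxima report their first index.
find_peaks <- function(counts, min_prominence = 0) {
  n <- length(counts)
  idx <- integer(0); hgt <- numeric(0); prom <- numeric(0)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && counts[j + 1L] == counts[i]) j <- j + 1L
    left_ok <- i == 1L || counts[i - 1L] < counts[i]
    right_ok <- j == n || counts[j + 1L] < counts[i]
    if (counts[i] > 0 && left_ok && right_ok) {
      lmin <- counts[i]
      k <- i - 1L
      while (k >= 1L && counts[k] < counts[i]) { lmin <- min(lmin, counts[k]); k <- k - 1L }
      if (k < 1L) lmin <- min(counts[seq_len(i)])
      rmin <- counts[i]
      k <- j + 1L
      while (k <= n && counts[k] < counts[i]) { rmin <- min(rmin, counts[k]); k <- k + 1L }
      if (k > n) rmin <- min(counts[j:n])
      p <- counts[i] - max(lmin, rmin)
      if (p >= min_prominence) {
        idx <- c(idx, i); hgt <- c(hgt, counts[i]); prom <- c(prom, p)
      }
    }
    i <- j + 1L
  }
  list(index = idx, height = hgt, prominence = prom)
}

#' @export
print.distance_distribution <- function(x, ...) {
  cat(sprintf("<distance_distribution: %d distances, bin %.2f px, %d peaks>\n",
              length(x$distances), x$bin_width, nrow(x$peaks)))
  if (nrow(x$peaks)) print(utils::head(x$peaks, 10))
  invisible(x)
}

#' Ranked candidate unit-cell lengths
#'
#' Returns the k smallest detected peak positions for user inspection. No
#' automatic choice of three lengths is made: same-length axes, near-multiple
#' axes and cross-cell combinations make the three shortest peaks an
#' unreliable automatic answer, so the accepted lengths are a user decision.
#'
#' @param dist A [pairwise_distances()] result.
#' @param k Number of candidates to return (default 6).
#' @return Data frame `position`, `height`, `prominence` of the k smallest
#'   peak positions, ascending; empty (with a warning) if no peaks.
#' @export
candidate_lengths <- function(dist, k = 6L) {
  pk <- dist$peaks
  if (nrow(pk) == 0L) {
    warning("no peaks detected in the distance distribution")
    return(pk)
  }
  pk[order(pk$position), ][seq_len(min(k, nrow(pk))), , drop = FALSE]
}

#' Expected cross-unit-cell peak positions
#'
#' For a cell hypothesis (a, b, c, α, β, γ in reciprocal px and degrees),
#' predicts the distances |m·u + p·w| for integer m, p up to `max_order` and
#' each axis pair (a,b), (a,c), (b,c), using the metric
#' |m u + p w|² = m²|u|² + p²|w|² + 2 m p |u||w| cos(angle). Comparing these
#' against the observed distance distribution verifies a choice of cell
#' lengths.
#'
#' @param cell List with `lengths = c(a, b, c)` (px) and
#'   `angles = c(alpha, beta, gamma)` (deg; angles between b-c, a-c, a-b).
#' @param max_order Maximum |m|, |p| (default 3).
#' @param dedup_tol Distances closer than this are reported once (default 1
#'   px, the histogram bin width).
#' @return Data frame `label`, `distance` (px), ascending by distance.
#' @export
predict_cross_peaks <- function(cell, max_order = 3L, dedup_tol = 1) {
  stopifnot(max_order >= 1L, all(cell$lengths > 0),
            all(cell$angles > 0 & cell$angles < 180))
  len <- cell$lengths; ang <- cell$angles * pi / 180
  axes <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  # angle between axis pair (i,j): gamma for (a,b), beta for (a,c), alpha for (b,c)
  pair_angle <- c(ang[3], ang[2], ang[1])
  nm <- c("a", "b", "c")
  out <- list()
  for (t in seq_along(axes)) {
    i <- axes[[t]][1]; j <- axes[[t]][2]
    for (m in -max_order:max_order) for (p in -max_order:max_order) {
      if (m == 0L && p == 0L) next
      if (m < 0L || (m == 0L && p < 0L)) next  # +/- give equal lengths
      if (p == 0L && t > 1L) next   # pure-a / pure-b already listed
      if (m == 0L && t == 3L) next  # pure-c already listed under (a,c)
      d2 <- m^2 * len[i]^2 + p^2 * len[j]^2 +
        2 * m * p * len[i] * len[j] * cos(pair_angle[t])
      out[[length(out) + 1L]] <- data.frame(
        label = sprintf("%+d%s%+d%s", m, nm[i], p, nm[j]),
        distance = sqrt(max(d2, 0)))
    }
  }
  df <- do.call(rbind, out)
  df <- df[order(df$distance, df$label), ]
  keep <- rep(TRUE, nrow(df))
  last <- -Inf
  for (r in seq_len(nrow(df))) {
    if (df$distance[r] - last < dedup_tol) keep[r] <- FALSE else last <- df$distance[r]
  }
  rownames(df) <- NULL
  df[keep, ]
}
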