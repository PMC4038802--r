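#' Difference vectors between all pairs of reciprocal-space spots
#'
#' @param v n x 3 matrix of reciprocal vectors (px), n >= 2.
#' @return m x 3 matrix of unordered-pair differences (m = n(n-1)/2), one
#'   orientation each (row j minus row i for i < j).
#' @export
difference_vectors <- function(v) {
  if (!is.matrix(v)) v <- matrix(v, ncol = 3L)
  n <- nrow(v)
  if (n < 2L) stop("at least 2 spots are required")
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  d <- v[ij[, 2], , drop = FALSE] - v[ij[, 1], , drop = FALSE]
  dimnames(d) <- list(NULL, c("vx", "vy", "vz"))
  d
}

#' Keep difference vectors whose length matches a unit-cell dimension
#'
#' @param vectors m x 3 matrix of difference vectors (px).
#' @param lengths The three accepted unit-cell lengths (px).
#' @param tol Relative length tolerance (default 0.05).
#' @return The rows of `vectors` whose norm is within `tol` of any length;
#'   warns if none survive.
#' @export
filter_by_length <- function(vectors, lengths, tol = 0.05) {
  stopifnot(tol > 0, length(lengths) == 3L, all(lengths > 0))
  if (!is.matrix(vectors)) vectors <- matrix(vectors, ncol = 3L)
  nrm <- sqrt(rowSums(vectors^2))
  ok <- Reduce(`|`, lapply(lengths, function(L) abs(nrm - L) / L <= tol))
  if (!any(ok)) warning("no difference vectors matched the cell lengths; ",
                        "check lengths and tolerance")
  vectors[ok, , drop = FALSE]
}

# Angle in degrees between rows of m and vector r, folding d and -d together
# (result in [0, 90]).
folded_angle <- function(m, r) {
  if (!is.matrix(m)) m <- matrix(m, ncol = 3L)
  cosang <- abs(m %*% r) / (sqrt(rowSums(m^2)) * sqrt(sum(r^2)))
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}

#' Cluster difference vectors into parallel groups and average them
#'
#' Each vector is first assigned to the nearest of four fixed reference
#' directions <1,0,0>, <0,1,0>, <0,0,1>, <1,1,0> (sign-agnostic), then
#' clustered within its assignment: a vector joins an existing group when it
#' is within `angular_tol` of the group's running mean direction and within
#' `length_tol` of its mean norm (the norm gate keeps e.g. a 2a* vector,
#' which survives length filtering against a c axis of similar length, from
#' polluting the a* group it is parallel to). Anti-parallel members are
#' flipped by multiplying by -1 before averaging.
#'
#' @param vectors m x 3 matrix of length-filtered difference vectors.
#' @param angular_tol Cluster half-angle in degrees, in (0, 45); default 8.
#' @param length_tol Relative norm tolerance within a group (default 0.05).
#' @return List of `vector_group` objects sorted by score (member count)
#'   descending; each has `mean` (length-3), `members` (matrix, flipped to
#'   the common hemisphere), `score`, `reference` (the reference direction
#'   label).
#' @export
group_and_average <- function(vectors, angular_tol = 8, length_tol = 0.05) {
  stopifnot(angular_tol > 0, angular_tol < 45)
  if (!is.matrix(vectors)) vectors <- matrix(vectors, ncol = 3L)
  refs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 0))
  ref_labels <- c("<100>", "<010>", "<001>", "<110>")
  ang <- sapply(seq_len(nrow(refs)), function(i) folded_angle(vectors, refs[i, ]))
  if (!is.matrix(ang)) ang <- matrix(ang, ncol = nrow(refs))
  assignment <- max.col(-ang, ties.method = "first")
  groups <- list()
  for (a in seq_len(nrow(refs))) {
    idx <- which(assignment == a)
    if (!length(idx)) next
    # deterministic order: by norm then components
    vv <- vectors[idx, , drop = FALSE]
    ord <- order(sqrt(rowSums(vv^2)), vv[, 1], vv[, 2], vv[, 3])
    vv <- vv[ord, , drop = FALSE]
    bucket <- list()
    for (r in seq_len(nrow(vv))) {
      d <- vv[r, ]
      placed <- FALSE
      for (g in seq_along(bucket)) {
        mn <- bucket[[g]]$sum / bucket[[g]]$n
        if (folded_angle(d, mn) <= angular_tol &&
            abs(sqrt(sum(d^2)) - sqrt(sum(mn^2))) / sqrt(sum(mn^2)) <= length_tol) {
          if (sum(d * mn) < 0) d <- -d  # flip to the common hemisphere
          bucket[[g]]$sum <- bucket[[g]]$sum + d
          bucket[[g]]$n <- bucket[[g]]$n + 1L
          bucket[[g]]$members <- rbind(bucket[[g]]$members, d)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        bucket[[length(bucket) + 1L]] <- list(sum = d, n = 1L,
                                              members = matrix(d, 1L))
      }
    }
    for (g in bucket) {
      groups[[length(groups) + 1L]] <- structure(
        list(mean = g$sum / g$n, members = g$members, score = g$n,
             reference = ref_labels[a]),
        class = "vector_group")
    }
  }
  scores <- vapply(groups, function(g) g$score, integer(1))
  groups[order(-scores)]
}

#' @export
print.vector_group <- function(x, ...) {
  cat(sprintf("<vector_group ref %s: mean (%.2f, %.2f, %.2f), |v| %.2f, score %d>\n",
              x$reference, x$mean[1], x$mean[2], x$mean[3],
              sqrt(sum(x$mean^2)), x$score))
  invisible(x)
}

# angle between two vectors folding v and -v (degrees, [0, 90])
vec_angle_folded <- function(u, w) folded_angle(matrix(u, 1L), w)

#' Choose the three unit-cell basis vectors among group candidates
#'
#' Ranks triples of group means by total score, subject to their norms
#' matching the target cell lengths and their pairwise angles matching the
#' target cell angles (sign-agnostic) within tolerance. The winning triple is
#' relabelled so each vector matches its target length slot, and the basis is
#' made right-handed by flipping the third vector if needed.
#'
#' @param groups List of `vector_group`s from [group_and_average()].
#' @param target_lengths `c(a, b, c)` accepted cell lengths (px).
#' @param target_angles `c(alpha, beta, gamma)` cell angles in degrees
#'   (between b-c, a-c, a-b); default 90, 90, 90.
#' @param length_tol Relative norm tolerance (default 0.05).
#' @param angle_tol Angle tolerance in degrees (default 8).
#' @param max_groups Consider at most this many top-score groups (default 12).
#' @return An object of class `unit_cell`: list with `basis` (3 x 3 matrix,
#'   rows a*, b*, c*), `score`, and `candidates` (data frame of all
#'   admissible triples for user override). Errors listing near misses when
#'   no admissible triple exists.
#' @export
select_cell_vectors <- function(groups, target_lengths,
                                target_angles = c(90, 90, 90),
                                length_tol = 0.05, angle_tol = 8,
                                max_groups = 12L) {
  if (length(groups) < 3L) stop("need at least 3 vector groups, have ",
                                length(groups))
  groups <- groups[seq_len(min(max_groups, length(groups)))]
  means <- t(vapply(groups, function(g) g$mean, numeric(3)))
  norms <- sqrt(rowSums(means^2))
  scores <- vapply(groups, function(g) g$score, integer(1))
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  # target angle between slot pair: (a,b)=gamma, (a,c)=beta, (b,c)=alpha
  slot_pairs <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  pair_target <- c(target_angles[3], target_angles[2], target_angles[1])
  fold_target <- pmin(pair_target, 180 - pair_target)
  cand <- list()
  near <- character(0)
  combs <- utils::combn(length(groups), 3L)
  for (ci in seq_len(ncol(combs))) {
    trip <- combs[, ci]
    for (pm in perms) {
      g <- trip[pm]  # g[s] = group filling slot s (a, b, c)
      len_dev <- abs(norms[g] - target_lengths) / target_lengths
      if (any(len_dev > length_tol)) next
      ang_dev <- vapply(seq_along(slot_pairs), function(t) {
        sp <- slot_pairs[[t]]
        abs(vec_angle_folded(means[g[sp[1]], ], means[g[sp[2]], ]) -
              fold_target[t])
      }, numeric(1))
      if (any(ang_dev > angle_tol)) {
        if (all(len_dev <= length_tol)) {
          near <- c(near, sprintf("groups (%s): angle deviation %.1f deg",
                                  paste(g, collapse = ","), max(ang_dev)))
        }
        next
      }
      cand[[length(cand) + 1L]] <- data.frame(
        g1 = g[1], g2 = g[2], g3 = g[3], score = sum(scores[g]),
        ang_dev = sum(ang_dev), len_dev = sum(len_dev))
    }
  }
  if (!length(cand)) {
    stop("no admissible basis triple found",
         if (length(near)) paste0("; near misses:\n  ",
                                  paste(utils::head(unique(near), 5),
                                        collapse = "\n  ")) else "")
  }
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$score, cand$ang_dev, cand$len_dev), ]
  rownames(cand) <- NULL
  best <- cand[1, ]
  basis <- means[c(best$g1, best$g2, best$g3), , drop = FALSE]
  if (det(basis) < 0) basis[3, ] <- -basis[3, ]  # right-handed
  rownames(basis) <- c("a*", "b*", "c*")
  structure(list(basis = basis, score = best$score, candidates = cand),
            class = "unit_cell")
}

#' @export
print.unit_cell <- function(x, ...) {
  n <- sqrt(rowSums(x$basis^2))
  cat(sprintf("<unit_cell: |a*| %.2f, |b*| %.2f, |c*| %.2f px; score %d>\n",
              n[1], n[2], n[3], x$score))
  invisible(x)
}

#' Lengths and angles of a reciprocal basis
#'
#' @param basis 3 x 3 matrix with rows a*, b*, c*.
#' @return List `lengths` (px) and `angles` (deg: alpha between b*-c*, beta
#'   a*-c*, gamma a*-b*).
#' @export
basis_parameters <- function(basis) {
  n <- sqrt(rowSums(basis^2))
  ang <- function(i, j) {
    acos(pmin(pmax(sum(basis[i, ] * basis[j, ]) / (n[i] * n[j]), -1), 1)) * 180 / pi
  }
  list(lengths = unname(n), angles = c(ang(2, 3), ang(1, 3), ang(1, 2)))
}
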