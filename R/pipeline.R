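#' Load a dataset directory (config, images, pick files)
#'
#' Expects `dataset.yaml`, the TIFF stills it lists, and per-image pick
#' files named `<image stem>_picks.txt` (as written by [make_pick_files()]
#' or by hand).
#'
#' @param dir Dataset directory.
#' @return List `config`, `images` (list of [tilt_image()], ascending tilt),
#'   `picks` (named list of `spot_list`s keyed by image id, possibly empty).
#' @export
load_dataset <- function(dir) {
  config_path <- file.path(dir, "dataset.yaml")
  meta <- read_dataset_config(config_path)
  paths <- file.path(dir, meta$images$file)
  images <- read_tilt_series(paths, config_path)
  picks <- list()
  for (im in images) {
    pp <- file.path(dir, sub("\\.tif$", "_picks.txt", im$id))
    if (file.exists(pp)) picks[[im$id]] <- read_spot_picks(pp)
  }
  list(config = meta$config, images = images, picks = picks)
}

# Beam center from every Friedel pair found in the pick files; NULL if none.
dataset_beam_center <- function(picks) {
  pairs <- do.call(c, lapply(picks, attr, "friedel_pairs"))
  if (is.null(pairs) || !length(pairs)) return(NULL)
  beam_center_from_friedel(pairs)
}

# All picked (role == "pick") spots lifted to reciprocal space.
picked_vectors <- function(images, picks, config) {
  vs <- list()
  for (im in images) {
    sl <- picks[[im$id]]
    if (is.null(sl)) next
    xy <- sl[sl$role == "pick", c("x", "y")]
    if (nrow(xy)) vs[[im$id]] <- spot_to_v(as.matrix(xy), im, config)
  }
  do.call(rbind, vs)
}

#' Run the full processing chain on a dataset directory
#'
#' Stages: beam-center determination from Friedel picks, reciprocal-vector
#' reconstruction of the picked spots, distance-distribution peak detection
#' (verified against the user-accepted cell lengths), difference-vector
#' clustering into initial unit-cell vectors, iterative refinement
#' (predict / mass-center / contrast-filter / recalculate), final indexing
#' without mass centering, intensity measurement, and 4/mmm merging. The
#' accepted cell lengths and angles are inputs, as in the original
#' workflow, where the cell was known a priori and the distance
#' distribution served as verification.
#'
#' @param dir Dataset directory (see [load_dataset()]).
#' @param accepted_lengths `c(a, b, c)` accepted reciprocal cell lengths in
#'   px; matched against detected peaks, then replaced by the matching peak
#'   positions so the cell actually used is the measured one.
#' @param accepted_angles Cell angles in degrees (default 90, 90, 90).
#' @param L Laue-zone threshold (default 0.15).
#' @param resolution_limit Prediction cutoff in Å (default 9).
#' @param box Measurement box edge, px (default 10).
#' @param refine_threshold,measure_threshold Contrast thresholds for the
#'   refinement and measurement stages (defaults 0.10, 0.005).
#' @param max_iter Refinement iteration cap (default 10).
#' @param cutoff Fractional merge cutoff; 1.0 (default) is max-only merging.
#' @param length_tol,angular_tol Clustering tolerances (defaults 0.05, 8).
#' @param write_output Write `reflections.txt` and `merge_stats.txt` into
#'   `dir` (default TRUE).
#' @return List `beam_center`, `distribution`, `peak_lengths` (matched peak
#'   positions), `initial_basis`, `refinement` (from [refine_cell()]),
#'   `basis`, `predictions` (per image), `measurements`, `merged`,
#'   `rmerge`, `reflections_path`.
#' @export
process_dataset <- function(dir, accepted_lengths,
                            accepted_angles = c(90, 90, 90),
                            L = 0.15, resolution_limit = 9, box = 10,
                            refine_threshold = 0.10,
                            measure_threshold = 0.005, max_iter = 10L,
                            cutoff = 1.0, length_tol = 0.05,
                            angular_tol = 8, write_output = TRUE) {
  ds <- load_dataset(dir)
  config <- ds$config

  bc <- dataset_beam_center(ds$picks)
  if (!is.null(bc)) {
    ds$images <- lapply(ds$images, function(im) { im$beam_center <- bc; im })
  }

  v <- picked_vectors(ds$images, ds$picks, config)
  if (is.null(v) || nrow(v) < 10L) {
    stop("too few picked spots (need pick files with 'pick' rows); ",
         "run spot picking (or make_pick_files on simulated truth) first")
  }
  dd <- pairwise_distances(v)
  cand <- candidate_lengths(dd, k = 10L)
  peak_lengths <- vapply(accepted_lengths, function(Lt) {
    i <- which.min(abs(cand$position - Lt))
    if (!length(i) || abs(cand$position[i] - Lt) / Lt > 0.05) {
      stop("no distance-distribution peak within 5% of accepted length ",
           Lt, " px; detected peaks: ",
           paste(round(cand$position, 1), collapse = ", "))
    }
    cand$position[i]
  }, numeric(1))

  diffs <- difference_vectors(v)
  filt <- filter_by_length(diffs, peak_lengths, length_tol)
  groups <- group_and_average(filt, angular_tol, length_tol)
  cell <- select_cell_vectors(groups, peak_lengths, accepted_angles,
                              length_tol, angular_tol)

  ref_xy <- lapply(ds$images, function(im) {
    sl <- ds$picks[[im$id]]
    if (is.null(sl)) return(NULL)
    attr(sl, "reference")
  })
  have_refs <- !vapply(ref_xy, is.null, logical(1))
  if (!any(have_refs)) stop("no image has two reference picks")
  imgs <- ds$images[have_refs]
  refs <- ref_xy[have_refs]

  refined <- refine_cell(imgs, refs, cell$basis, config, L,
                         resolution_limit, box, threshold = refine_threshold,
                         max_iter = max_iter)

  predictions <- list()
  meas <- list()
  for (i in seq_along(imgs)) {
    pred <- index_image(refs[[i]], refined$basis, imgs[[i]], config, L,
                        resolution_limit)
    predictions[[imgs[[i]]$id]] <- pred
    meas[[i]] <- measure_intensities(imgs[[i]], pred, box, measure_threshold)
  }
  measurements <- do.call(rbind, meas)
  merged <- merge_threshold(measurements, cutoff)

  reflections_path <- NULL
  if (write_output) {
    reflections_path <- file.path(dir, "reflections.txt")
    write_reflections(merged$reflections, reflections_path)
    utils::write.table(merge_statistics(measurements),
                       file.path(dir, "merge_stats.txt"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  list(beam_center = bc, distribution = dd, peak_lengths = peak_lengths,
       initial_basis = cell$basis, refinement = refined,
       basis = refined$basis, predictions = predictions,
       measurements = measurements, merged = merged$reflections,
       rmerge = merged$rmerge, reflections_path = reflections_path)
}

#' Reindexing transform between two bases of the same lattice
#'
#' Two valid bases of one reciprocal lattice differ by a unimodular integer
#' matrix T with `hkl_2 = hkl_1 %*% T`; for a tetragonal cell T is typically
#' a signed permutation within the Laue group. Errors if the bases do not
#' describe the same lattice.
#'
#' @param basis Recovered 3 x 3 basis.
#' @param true_basis Reference 3 x 3 basis.
#' @param tol Maximum deviation of T's entries from integers (default 0.1).
#' @return 3 x 3 integer matrix T.
#' @export
index_transform <- function(basis, true_basis, tol = 0.1) {
  Tm <- basis %*% solve(true_basis)
  Ti <- round(Tm)
  if (max(abs(Tm - Ti)) > tol || abs(abs(det(Ti)) - 1) > 1e-9) {
    stop("bases are not related by a unimodular integer transform")
  }
  storage.mode(Ti) <- "integer"
  Ti
}

#' Compare final indexing against a simulation ground truth
#'
#' Matches measured (or predicted) spots to rendered ground-truth
#' reflections by detector position and tallies Miller-index agreement.
#'
#' @param spots Data frame with columns `h k l x y` and an image identifier
#'   column `image_id` (measurements) or an `indexing_result` with its
#'   `image_id` attribute.
#' @param truth Ground-truth table from [simulate_tilt_series()] (its
#'   `file` column is the image identifier).
#' @param transform Optional unimodular matrix from [index_transform()]
#'   mapping the spots' indices onto the truth's indexing convention.
#' @param tol_px Position-match radius in px (default 2).
#' @return List `n_spots`, `n_matched` (spots over a rendered reflection),
#'   `n_correct` (matched and index equal), `accuracy` (correct / matched),
#'   `coverage` (rendered unmasked truth reflections recovered with the
#'   correct index / total).
#' @export
hkl_agreement <- function(spots, truth, transform = NULL, tol_px = 2) {
  if (inherits(spots, "indexing_result")) {
    spots <- data.frame(spots, image_id = attr(spots, "image_id"))
  }
  if (!is.null(transform)) {
    hkl <- as.matrix(spots[, c("h", "k", "l")]) %*% transform
    spots$h <- hkl[, 1]; spots$k <- hkl[, 2]; spots$l <- hkl[, 3]
  }
  n_matched <- 0L; n_correct <- 0L
  covered <- logical(nrow(truth))
  for (i in seq_len(nrow(spots))) {
    tt <- which(truth$file == spots$image_id[i])
    if (!length(tt)) next
    d2 <- (truth$x[tt] - spots$x[i])^2 + (truth$y[tt] - spots$y[i])^2
    j <- tt[which.min(d2)]
    if (min(d2) > tol_px^2) next
    n_matched <- n_matched + 1L
    if (truth$h[j] == spots$h[i] && truth$k[j] == spots$k[i] &&
        truth$l[j] == spots$l[i]) {
      n_correct <- n_correct + 1L
      covered[j] <- TRUE
    }
  }
  eligible <- !truth$masked
  list(n_spots = nrow(spots), n_matched = n_matched, n_correct = n_correct,
       accuracy = if (n_matched) n_correct / n_matched else NA_real_,
       coverage = sum(covered[eligible]) / sum(eligible))
}

#' Compare a recovered basis with the true one
#'
#' Accounts for the valid relabelings and sign flips of a basis: matches
#' each recovered vector to the true vector minimizing total folded angle.
#'
#' @param basis Recovered 3 x 3 basis.
#' @param true_basis True 3 x 3 basis.
#' @return List `angle_deg` (per matched vector) and `norm_rel` (relative
#'   norm error per vector).
#' @export
basis_error <- function(basis, true_basis) {
  m <- match_basis(basis, true_basis)
  nrm_t <- sqrt(rowSums(true_basis^2))
  nrm_m <- sqrt(rowSums(m$basis^2))
  list(angle_deg = m$angle_delta, norm_rel = abs(nrm_m - nrm_t) / nrm_t)
}
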