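test_that("reference spots index by inverse cell matrix with rounding residuals", {
  cfg <- instrument_config(0.025, 4000, c(1024L, 1024L))
  ctr <- c(511.5, 511.5)
  im <- flat_image(1024, tilt_deg = 0, center = ctr)
  B <- diag(c(50, 50, 100))
  # exact lattice point (2,1,0) at offset (100, 50); z from the sagitta is
  # negligible at this radius
  refs <- index_reference_spots(rbind(ctr + c(100, 50), ctr + c(50, 100)),
                                B, im, cfg)
  expect_equal(unname(refs$hkl[1, ]), c(2L, 1L, 0L))
  expect_equal(unname(refs$hkl[2, ]), c(1L, 2L, 0L))
  expect_lt(max(refs$residual), 0.01)

  refs2 <- index_reference_spots(rbind(ctr + c(101, 49), ctr + c(50, 100)),
                                 B, im, cfg)
  expect_equal(unname(refs2$hkl[1, ]), c(2L, 1L, 0L))
  expect_equal(unname(refs2$residual[1, 1:2]), c(0.02, 0.02),
               tolerance = 1e-6)

  # half-integer position: maximal rounding ambiguity triggers the warning
  expect_warning(
    index_reference_spots(rbind(ctr + c(75, 0), ctr + c(0, 50)), B, im, cfg),
    "indexes poorly")
})

test_that("the check vector is the integer cross product of the references", {
  expect_equal(compute_check_vector(c(1, 0, 0), c(0, 1, 0)), c(0L, 0L, 1L))
  expect_equal(compute_check_vector(c(2, 1, 0), c(1, 2, 0)), c(0L, 0L, 3L))
  expect_error(compute_check_vector(c(1, 0, 0), c(2, 0, 0)), "collinear")
})

test_that("the central Laue zone predicts exactly the in-plane indices", {
  cfg <- instrument_config(0.025, 4000, c(1024L, 1024L))
  im <- flat_image(1024, tilt_deg = 0)
  B <- diag(c(50, 50, 100))
  pred <- predict_spots(B, q = c(0L, 0L, 1L), L = 0.15, im, cfg,
                        resolution_limit = 10)
  expect_true(all(pred$l == 0))
  r_max <- radius_at_resolution(10, cfg)
  expect_true(all(pred$r_px <= r_max + 1e-9))
  grid <- expand.grid(h = -8:8, k = -8:8)
  expected <- grid[sqrt((grid$h * 50)^2 + (grid$k * 50)^2) <= r_max &
                     (grid$h != 0 | grid$k != 0), ]
  expect_equal(nrow(pred), nrow(expected))
})

test_that("prediction sets are nested as the Laue threshold grows", {
  cfg <- instrument_config(0.025, 4000, c(1024L, 1024L))
  im <- flat_image(1024, tilt_deg = 12)
  B <- diag(c(50, 50, 100)) %*% t(tilt_rotation(4, 20))
  q <- c(1L, 2L, 9L)  # primitive, |q| ~ 9.3: both L steps open new zones
  keys <- lapply(c(0.05, 0.15, 0.30), function(L) {
    p <- predict_spots(B, q, L, im, cfg, resolution_limit = 8)
    paste(p$h, p$k, p$l)
  })
  expect_true(all(keys[[1]] %in% keys[[2]]))
  expect_true(all(keys[[2]] %in% keys[[3]]))
  expect_lt(length(keys[[1]]), length(keys[[2]]))
  expect_lt(length(keys[[2]]), length(keys[[3]]))
})

test_that("both reference spots appear in their own prediction set", {
  ms <- mini_sim()
  ds <- load_dataset(ms$dir)
  has_ref <- vapply(ds$images, function(im)
    !is.null(attr(ds$picks[[im$id]], "reference")), logical(1))
  im <- ds$images[[which(has_ref)[1]]]
  ref_xy <- attr(ds$picks[[im$id]], "reference")
  pred <- index_image(ref_xy, mini_truth_basis(), im, ds$config,
                      L = 0.15, resolution_limit = mini_resolution)
  ref_hkl <- attr(pred, "ref_hkl")
  keys <- paste(pred$h, pred$k, pred$l)
  expect_true(all(paste(ref_hkl[, 1], ref_hkl[, 2], ref_hkl[, 3]) %in% keys))
})

test_that("with the true cell and references, rendered in-zone spots are recovered", {
  ms <- mini_sim()
  ds <- load_dataset(ms$dir)
  truth <- ms$sim$truth
  covs <- c(); accs <- c()
  for (im in ds$images) {
    ref_xy <- attr(ds$picks[[im$id]], "reference")
    if (is.null(ref_xy)) next
    pred <- index_image(ref_xy, mini_truth_basis(), im, ds$config,
                        L = 0.15, resolution_limit = mini_resolution)
    q <- attr(pred, "q")
    tt <- truth[truth$file == im$id & !truth$masked, ]
    r <- sqrt((tt$x - im$beam_center[1])^2 + (tt$y - im$beam_center[2])^2)
    zone <- abs(as.matrix(tt[, c("h", "k", "l")]) %*% q) / sqrt(sum(q^2))
    tt <- tt[zone <= 0.15 & r <= radius_at_resolution(mini_resolution,
                                                      ds$config), ]
    if (nrow(tt) < 3) next
    a <- hkl_agreement(pred, tt, tol_px = 1.5)
    covs <- c(covs, a$coverage); accs <- c(accs, a$accuracy)
  }
  expect_gte(mean(covs), 0.95)
  expect_equal(accs, rep(1, length(accs)))  # zero mis-assignments
})

test_that("displacing the reference picks degrades prediction coverage", {
  ms <- mini_sim()
  ds <- load_dataset(ms$dir)
  truth <- ms$sim$truth
  cov_of <- function(shift) {
    covs <- c()
    for (im in ds$images) {
      ref_xy <- attr(ds$picks[[im$id]], "reference")
      if (is.null(ref_xy)) next
      pred <- suppressWarnings(
        index_image(ref_xy + shift, mini_truth_basis(), im, ds$config,
                    L = 0.15, resolution_limit = mini_resolution))
      tt <- truth[truth$file == im$id & !truth$masked, ]
      covs <- c(covs, hkl_agreement(pred, tt, tol_px = 1.5)$coverage)
    }
    mean(covs)
  }
  expect_gte(cov_of(0), cov_of(matrix(c(3, -3, -3, 3), 2)))
})
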