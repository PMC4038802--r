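test_that("mass centering lands on a bright pixel and keeps stable spots", {
  px <- matrix(0, 64, 64)
  px[31 + 1, 33 + 1] <- 100  # 0-based (x=33, y=31): offset (+1, -1) from start
  mc <- mass_center(px, start = c(32, 32), box = 10, max_shift = 2)
  expect_true(mc$kept)
  expect_equal(mc$center, c(33, 31))
  expect_equal(mc$shift2, 0)
})

test_that("a flat box is a fixed point of mass centering", {
  px <- matrix(7, 64, 64)
  mc <- mass_center(px, start = c(32, 32), box = 10, max_shift = 2)
  expect_true(mc$kept)
  expect_equal(mc$shift2, 0)
  expect_equal(mc$center, c(32, 32))  # argmax ties resolve toward the center
})

test_that("a spot that walks between maxima on the second pass is discarded", {
  px <- matrix(0, 64, 64)
  # moderate peak inside the first box, brighter peak revealed only after
  # recentering: the second pass jumps 4 px and the spot is dropped
  px[32 + 1, 36 + 1] <- 10
  px[32 + 1, 40 + 1] <- 20
  mc <- mass_center(px, start = c(32, 32), box = 10, max_shift = 2)
  expect_false(mc$kept)
  expect_equal(mc$reason, "walked")
  expect_gt(mc$shift2, 2)
})

test_that("boxes leaving the raster discard the spot with a flag", {
  px <- matrix(0, 32, 32)
  mc <- mass_center(px, start = c(2, 16), box = 10, max_shift = 2)
  expect_false(mc$kept)
  expect_equal(mc$reason, "off_raster")
})

test_that("contrast ratio separates spots from background, boundary inclusive", {
  uni <- matrix(100, 64, 64)
  cf <- contrast_filter(uni, c(32, 32), box = 10, threshold = 0.01)
  expect_false(cf$keep)
  expect_equal(cf$measurement$ratio, 0)

  # circle mean 110, background 100: ratio exactly 0.10 is kept
  px <- matrix(100, 64, 64)
  gx <- matrix(0:63, 64, 64, byrow = TRUE); gy <- matrix(0:63, 64, 64)
  px[(gx - 32)^2 + (gy - 32)^2 <= 25] <- 110
  cf2 <- contrast_filter(px, c(32, 32), box = 10, threshold = 0.10)
  expect_true(cf2$keep)
  expect_equal(cf2$measurement$ratio, 0.10, tolerance = 1e-9)

  # monotone in the threshold: a discarded spot stays discarded
  expect_false(contrast_filter(px, c(32, 32), 10, 0.11)$keep)
})

test_that("a Gaussian spot's contrast matches the analytic expectation", {
  B <- 200; I <- 5e4; sigma <- 1.5
  px <- add_gaussian(matrix(B, 64, 64), 32, 32, sigma, I)
  m <- box_measurement(px, c(32, 32), box = 10)
  # analytic: fraction of I inside radius-5 circle over the circle area
  frac_in <- 1 - exp(-25 / (2 * sigma^2))
  expected_ratio <- (I * frac_in / m$n_circle) /
    (B + I * (1 - frac_in) / m$n_background)
  expect_equal(m$ratio, expected_ratio, tolerance = 0.02)
})

test_that("recalculated vectors reproduce an exact lattice to float precision", {
  set.seed(20)
  B <- rbind(c(52, 3, -1), c(-2, 58, 2), c(4, -1, 95))
  hkl <- unique(matrix(sample(-3:3, 3 * 200, replace = TRUE), ncol = 3))
  v <- hkl %*% B
  out <- recalculate_vectors(v, previous = B + matrix(rnorm(9, sd = 0.3), 3))
  expect_false(out$degenerate)
  expect_equal(unname(out$basis), unname(B), tolerance = 1e-6)
  # second run on converged data reports deltas below tolerance
  out2 <- recalculate_vectors(v, previous = out$basis)
  expect_lt(max(out2$angle_delta), 0.01)
  expect_lt(max(out2$norm_delta), 1e-4)
})

test_that("a degenerate refined set keeps the previous basis with a warning", {
  B <- diag(c(50, 60, 90))
  v <- matrix(rnorm(30, sd = 2), ncol = 3)  # no cell structure at all
  w <- capture_warnings(out <- recalculate_vectors(v, previous = B))
  expect_match(w, "degenerate", all = FALSE)
  expect_true(out$degenerate)
  expect_equal(out$basis, B)
})

test_that("the polish step can be disabled", {
  set.seed(21)
  B <- diag(c(40, 60, 90))
  hkl <- unique(matrix(sample(-3:3, 3 * 150, replace = TRUE), ncol = 3))
  v <- hkl %*% B + matrix(rnorm(3 * nrow(hkl), sd = 0.1), ncol = 3)
  a <- recalculate_vectors(v, B, polish = FALSE)
  b <- recalculate_vectors(v, B, polish = TRUE)
  expect_false(a$degenerate); expect_false(b$degenerate)
  expect_equal(unname(a$basis), unname(B), tolerance = 0.01)
  expect_equal(unname(b$basis), unname(B), tolerance = 0.01)
})

test_that("iterative refinement converges on the compact synthetic series", {
  ms <- mini_sim()
  ds <- load_dataset(ms$dir)
  bc <- microedr:::dataset_beam_center(ds$picks)
  ds$images <- lapply(ds$images, function(im) { im$beam_center <- bc; im })
  rx <- lapply(ds$images, function(im) attr(ds$picks[[im$id]], "reference"))
  keep <- !vapply(rx, is.null, logical(1))
  start <- mini_truth_basis() * (1 + 0.01) + 0.3  # a deliberately off start
  out <- refine_cell(ds$images[keep], rx[keep], start, ds$config,
                     L = 0.15, resolution_limit = mini_resolution)
  it <- out$iterations
  expect_lte(nrow(it), 10)
  # the large initial correction shrinks and stays small; the loop detects
  # the pixel-quantisation limit cycle instead of spinning to max_iter
  expect_lt(it$max_angle_delta[nrow(it)], it$max_angle_delta[1] / 2)
  expect_true(all(it$max_angle_delta[-1] <= it$max_angle_delta[1] / 2))
  expect_true(all(it$max_norm_delta[-1] <= 0.005))
  err <- basis_error(out$basis, mini_truth_basis())
  expect_lt(max(err$angle_deg), 2)
  expect_lt(max(err$norm_rel), 0.02)
})
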