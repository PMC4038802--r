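# Independent 16-operation oracle for Laue group 4/mmm, as explicit matrices.
ops_4mmm <- local({
  r4 <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  r2x <- diag(c(1, -1, -1))
  ops <- list(diag(3))
  for (i in 1:3) ops[[i + 1]] <- ops[[i]] %*% r4
  ops <- c(ops, lapply(ops, function(m) m %*% r2x))
  c(ops, lapply(ops, function(m) -m))
})

orbit_oracle <- function(hkl) {
  u <- unique(t(vapply(ops_4mmm, function(m) as.integer(m %*% hkl),
                       integer(3))))
  u[order(u[, 1], u[, 2], u[, 3]), , drop = FALSE]
}

sort_orbit <- function(m) m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]

test_that("4/mmm orbits match brute-force enumeration of the 16 operations", {
  expect_equal(nrow(p422_orbit(c(0, 0, 0))), 1)
  expect_equal(nrow(p422_orbit(c(1, 2, 3))), 16)
  expect_equal(unname(sort_orbit(p422_orbit(c(0, 0, 5)))),
               rbind(c(0L, 0L, -5L), c(0L, 0L, 5L)))
  set.seed(30)
  for (i in 1:25) {
    hkl <- sample(-4:4, 3, replace = TRUE)
    expect_equal(unname(sort_orbit(p422_orbit(hkl))),
                 unname(orbit_oracle(hkl)))
  }
})

test_that("every orbit member maps to the same canonical representative", {
  set.seed(31)
  for (i in 1:20) {
    hkl <- sample(-5:5, 3, replace = TRUE)
    orb <- p422_orbit(hkl)
    canon <- canonical_hkl_p422(hkl)
    expect_true(any(apply(orb, 1, function(r) all(r == canon))))
    for (j in seq_len(nrow(orb))) {
      expect_equal(canonical_hkl_p422(orb[j, ]), canon)
    }
  }
})

meas_df <- function(hkl_list, I) {
  m <- do.call(rbind, hkl_list)
  data.frame(h = m[, 1], k = m[, 2], l = m[, 3], I = I,
             image_id = seq_along(I))
}

test_that("max-only merging keeps the largest measurement per orbit", {
  meas <- meas_df(list(c(1, 2, 3), c(2, -1, 3), c(-1, -2, 3)), c(10, 8, 3))
  out <- merge_maxonly(meas)
  expect_equal(nrow(out), 1)
  expect_equal(out$I, 10)
  expect_equal(out$n, 3L)
  expect_equal(out$F, sqrt(10))

  single <- merge_maxonly(meas_df(list(c(2, 1, 0)), 7))
  expect_equal(single$I, 7)
  expect_equal(single$SigI, sqrt(7))
  expect_equal(single$SigF, sqrt(sqrt(7)))

  shuffled <- merge_maxonly(meas[c(3, 1, 2), ])
  expect_equal(shuffled, out)
})

test_that("threshold merging reproduces the hand-worked orbit arithmetic", {
  meas <- meas_df(list(c(1, 2, 3), c(2, -1, 3), c(-1, -2, 3)), c(10, 8, 3))
  m1 <- merge_threshold(meas, 1.0)
  expect_equal(m1$reflections$I, 10)  # cutoff 1.0 == max-only
  expect_equal(m1$reflections$n, 1L)
  expect_true(is.na(m1$rmerge))

  m05 <- merge_threshold(meas, 0.5)
  expect_equal(m05$reflections$I, 9)       # mean of {10, 8}
  expect_equal(m05$reflections$n, 2L)
  expect_equal(m05$rmerge, 2 / 18)         # (|10-9|+|8-9|) / (10+8)
  expect_equal(m05$reflections$SigI, sd(c(10, 8)))

  expect_error(merge_threshold(meas, 0), "cutoff")
  expect_error(merge_threshold(meas, 1.5), "cutoff")
})

test_that("cutoff 1.0 equals max-only over many random orbits", {
  set.seed(32)
  rows <- lapply(1:1000, function(i) {
    hkl <- sample(-5:5, 3, replace = TRUE)
    orb <- p422_orbit(hkl)
    picks <- orb[sample(nrow(orb), sample(1:4, 1), replace = TRUE), ,
                 drop = FALSE]
    data.frame(h = picks[, 1], k = picks[, 2], l = picks[, 3],
               I = round(runif(nrow(picks), 1, 1000), 2))
  })
  meas <- do.call(rbind, rows)
  a <- merge_maxonly(meas)
  b <- merge_threshold(meas, 1.0)$reflections
  expect_equal(a$I, b$I)
  expect_equal(a[, c("h", "k", "l")], b[, c("h", "k", "l")])
})

test_that("identical repeated measurements give Rmerge zero", {
  meas <- meas_df(list(c(1, 2, 3), c(-1, -2, 3), c(2, 0, 1), c(0, 2, 1)),
                  c(50, 50, 20, 20))
  m <- merge_threshold(meas, 0.1)
  expect_equal(m$rmerge, 0)
})

test_that("lowering the cutoff never shrinks any orbit's kept count", {
  set.seed(33)
  meas <- do.call(rbind, lapply(1:50, function(i) {
    hkl <- sample(-4:4, 3, replace = TRUE)
    orb <- p422_orbit(hkl)
    picks <- orb[sample(nrow(orb), 3, replace = TRUE), , drop = FALSE]
    data.frame(h = picks[, 1], k = picks[, 2], l = picks[, 3],
               I = runif(3, 1, 100))
  }))
  prev <- NULL
  for (cf in c(1.0, 0.75, 0.5, 0.25, 0.1)) {
    out <- merge_threshold(meas, cf)$reflections
    if (!is.null(prev)) {
      m <- merge(prev, out, by = c("h", "k", "l"))
      expect_true(all(m$n.y >= m$n.x))
    }
    prev <- out
  }
})

test_that("merging is invariant under a symmetry relabeling of the input", {
  set.seed(34)
  meas <- do.call(rbind, lapply(1:40, function(i) {
    hkl <- sample(-4:4, 3, replace = TRUE)
    data.frame(h = hkl[1], k = hkl[2], l = hkl[3], I = runif(1, 1, 500))
  }))
  op <- ops_4mmm[[7]]
  relabeled <- meas
  m2 <- t(op %*% t(as.matrix(meas[, c("h", "k", "l")])))
  relabeled$h <- m2[, 1]; relabeled$k <- m2[, 2]; relabeled$l <- m2[, 3]
  for (cf in c(1.0, 0.5)) {
    a <- merge_threshold(meas, cf)
    b <- merge_threshold(relabeled, cf)
    expect_equal(a$reflections, b$reflections)
    expect_equal(a$rmerge, b$rmerge)
  }
})

test_that("negative merged intensities clamp to zero before the square root", {
  meas <- meas_df(list(c(3, 1, 0)), -5)
  out <- merge_maxonly(meas)
  expect_equal(out$I, -5)   # the raw value is preserved in the record
  expect_equal(out$F, 0)
})

test_that("measured intensity recovers a noiseless Gaussian within 2 percent", {
  B <- 100; I <- 1e4; sigma <- 1.2
  px <- add_gaussian(matrix(B, 64, 64), 30, 34, sigma, I)
  m <- measure_intensity(px, c(30, 34), box = 10, threshold = 0.005)
  expect_true(m$recorded)
  expect_equal(m$I, I, tolerance = 0.02)

  flat <- measure_intensity(matrix(B, 64, 64), c(32, 32), 10, 0.005)
  expect_false(flat$recorded)
  expect_equal(flat$I, 0, tolerance = 1e-9)

  off <- measure_intensity(px, c(2, 2), 10, 0.005)
  expect_equal(off$reason, "off_raster")
})

test_that("a sloped background biases the sum by its curvature, not its slope", {
  B <- 100; I <- 2e4; sigma <- 1.2
  gx <- matrix(0:63, 64, 64, byrow = TRUE)
  lin <- B + 0.8 * (gx - 32)           # linear gradient through the center
  m <- measure_intensity(add_gaussian(lin, 32, 32, sigma, I), c(32, 32), 10)
  # symmetric regions cancel a linear term exactly
  expect_equal(m$I, I, tolerance = 0.02)

  quad <- B + 0.1 * (gx - 32)^2        # curved background is not cancelled
  mq <- measure_intensity(add_gaussian(quad, 32, 32, sigma, I), c(32, 32), 10)
  # independent arithmetic oracle for the curvature bias over the same
  # box/circle geometry
  xs <- 27:37; ys <- 27:37
  inc <- outer(ys - 32, xs - 32, function(a, b) a^2 + b^2 <= 25)
  bgv <- matrix(0.1 * (rep(xs, each = length(ys)) - 32)^2, nrow = length(ys))
  bias <- sum(bgv[inc]) - sum(inc) * mean(bgv[!inc])
  expect_equal(mq$I - I, bias, tolerance = 0.02 * I)
})
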