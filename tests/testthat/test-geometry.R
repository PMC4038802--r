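# Independent sagitta oracle: the depth of a sphere of radius R below its
# tangent plane at in-plane radius r, via the subtended angle.
sagitta_oracle <- function(r, R) R * (1 - cos(asin(r / R)))

test_that("ewald_z matches the closed-form sphere sagitta", {
  cfg <- instrument_config(0.025, 4000)
  expect_equal(ewald_z(c(0, 0), cfg), 0)
  # lambda 0.025 A, c 4000 px*A, r 2000 px: sphere radius 160000 px
  z <- ewald_z(c(2000, 0), cfg)
  expect_equal(z, sagitta_oracle(2000, 160000), tolerance = 1e-12)
  expect_equal(z, 12.5005, tolerance = 1e-4)
  za <- ewald_z(c(2000, 0), cfg, form = "small_angle")
  expect_equal(za, 12.5, tolerance = 1e-9)
  expect_lt(abs(z - za), 0.01)
  # only the in-plane radius matters
  expect_equal(ewald_z(c(0, 2000), cfg), z)
  expect_equal(ewald_z(c(2000 / sqrt(2), 2000 / sqrt(2)), cfg), z)
})

test_that("ewald_z rejects offsets beyond the sphere equator", {
  cfg <- instrument_config(0.5, 10)  # tiny sphere: radius 20 px
  expect_error(ewald_z(c(25, 0), cfg), "equator")
  expect_silent(ewald_z(c(19, 0), cfg))
})

test_that("exact and small-angle forms agree to 0.2 px at 2 A and diverge monotonically", {
  for (lam in c(0.02, 0.025, 0.033)) {
    cfg <- instrument_config(lam, 4000)
    r2A <- radius_at_resolution(2.0, cfg)
    d <- abs(ewald_z(c(r2A, 0), cfg) - ewald_z(c(r2A, 0), cfg, "small_angle"))
    expect_lt(d, 0.2)
  }
  cfg <- instrument_config(0.033, 4000)
  rr <- seq(200, 2400, by = 200)
  div <- ewald_z(cbind(rr, 0), cfg) - ewald_z(cbind(rr, 0), cfg, "small_angle")
  expect_true(all(diff(div) > 0))
})

test_that("spot_to_v applies the tilt rotation about the configured axis", {
  cfg <- instrument_config(0.025, 4000, c(1024L, 1024L))
  ctr <- c(511.5, 511.5)
  im0 <- tilt_image(matrix(0, 1024, 1024), 0, ctr)
  v <- spot_to_v(ctr + c(100, 0), im0, cfg)
  expect_equal(v[1, 1:2], c(vx = 100, vy = 0))
  expect_equal(unname(v[1, 3]), unname(ewald_z(c(100, 0), cfg)))

  # quarter turn about the y (tilt) axis sends +x to -z or +z
  im90 <- tilt_image(matrix(0, 1024, 1024), 90, ctr)
  v90 <- spot_to_v(ctr + c(100, 0), im90, cfg)
  expect_equal(unname(abs(v90[1, 3])), 100, tolerance = 1e-3)
  expect_equal(unname(v90[1, 2]), 0, tolerance = 1e-9)
  expect_lt(abs(v90[1, 1]), 0.05)
})

test_that("the tilt rotation preserves norms over random draws", {
  cfg <- instrument_config(0.025, 4000, c(1024L, 1024L))
  set.seed(42)
  n <- 1000
  xy <- matrix(runif(2 * n, 100, 900), ncol = 2)
  th <- runif(n, -70, 70)
  for (i in sample(n, 50)) {
    im <- tilt_image(matrix(0, 1024, 1024), th[i], c(511.5, 511.5))
    v <- spot_to_v(xy[i, ], im, cfg)
    d <- xy[i, ] - c(511.5, 511.5)
    expect_equal(sqrt(sum(v^2)),
                 sqrt(sum(d^2) + ewald_z(d, cfg)^2),
                 tolerance = 1e-9)
  }
})

test_that("project_to_detector inverts spot_to_v for on-sphere spots", {
  cfg <- instrument_config(0.025, 4000, c(1024L, 1024L))
  set.seed(7)
  n <- 1000
  xy <- matrix(runif(2 * n, 50, 973), ncol = 2)
  th <- runif(n, -60, 60)
  err <- vapply(seq_len(n), function(i) {
    im <- tilt_image(matrix(0, 1024, 1024), th[i], c(511.5, 511.5))
    v <- spot_to_v(xy[i, ], im, cfg)
    back <- project_to_detector(v, th[i], cfg) + rep(c(511.5, 511.5),
                                                     each = 1)
    max(abs(back - xy[i, , drop = FALSE]))
  }, numeric(1))
  expect_lt(max(err), 0.5)

  # theta = 0 passthrough drops the out-of-plane component without error
  p <- project_to_detector(c(50, -30, 0), 0, cfg)
  expect_equal(unname(p[1, ]), c(50, -30))
  p2 <- project_to_detector(c(50, -30, 400), 0, cfg)
  expect_equal(unname(p2[1, ]), c(50, -30))
})

test_that("flipping the z convention leaves pairwise distances unchanged", {
  set.seed(9)
  v <- matrix(rnorm(60, sd = 100), ncol = 3)
  vflip <- v
  vflip[, 3] <- -vflip[, 3]
  expect_equal(as.numeric(dist(v)), as.numeric(dist(vflip)))
})

test_that("beam center is the mean of Friedel-pair midpoints", {
  expect_equal(beam_center_from_friedel(rbind(c(100, 100), c(300, 300))),
               c(200, 200))
  pairs <- list(rbind(c(100, 100), c(300, 300)),
                rbind(c(150, 90), c(250, 310)))
  expect_equal(beam_center_from_friedel(pairs), c(200, 200))
  expect_error(beam_center_from_friedel(list()), "at least one")
  expect_error(beam_center_from_friedel(rbind(c(5, 5), c(5, 5))),
               "degenerate")
})
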