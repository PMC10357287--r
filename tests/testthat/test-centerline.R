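test_that("centerline construction validates its invariants", {
  expect_error(centerline(matrix(0, 1, 3), 7), "at least 2")
  expect_error(centerline(rbind(c(0, 0, 0), c(0, 0, 0)), 7), "distinct")
  expect_error(centerline(rbind(c(0, 0, 0), c(1, 0, 0)), c(7, -1)),
               "positive")
  expect_error(centerline(rbind(c(0, 0, 0), c(1, 0, 0)), 7,
                          landmarks = c(puncture = 5L)), "landmark")
})

test_that("imputed cross-sections obey the circular idealization", {
  cl <- centerline(cbind(0, 0, 0:10), diameter = 6.8)
  expect_equal(cl$sections$area, rep(pi * 3.4^2, 11), tolerance = 1e-9)
  expect_equal(cl$sections$perimeter, rep(pi * 6.8, 11), tolerance = 1e-9)
  expect_setequal(attr(cl, "imputed"), c("area", "perimeter"))
})

test_that("resampling a straight segment yields collinear 1 mm steps with fixed endpoints", {
  cl <- centerline(rbind(c(0, 0, 0), c(3, 0, 0), c(10, 0, 0)), 7)
  rs <- resample_smooth(cl, spacing = 1, window = 5)
  expect_equal(nrow(rs$points), 11L)
  expect_equal(rs$points[1, ], c(x = 0, y = 0, z = 0))
  expect_equal(rs$points[11, ], c(x = 10, y = 0, z = 0))
  expect_equal(diff(rs$points[, 1]), rep(1, 10), tolerance = 1e-9)
  expect_true(all(abs(rs$points[, 2:3]) < 1e-12))
})

test_that("window = 0 resampling stays on the original polyline", {
  cl <- centerline(rbind(c(0, 0, 0), c(10, 0, 0), c(10, 10, 0)), 7)
  rs <- resample_smooth(cl, spacing = 1, window = 0)
  ## every point must lie on one of the two legs (y = 0 or x = 10)
  off <- pmin(abs(rs$points[, 2]), abs(rs$points[, 1] - 10))
  expect_true(all(off < 1e-9))
})

test_that("smoothed resampling stays within half a spacing of a true circular arc", {
  pts <- arc_points(R = 50, ang = pi / 2, n = 50)
  cl <- centerline(pts, 7)
  rs <- resample_smooth(cl, spacing = 1, window = 3)
  dev_from_arc <- abs(sqrt((rs$points[, 1] - 0)^2 +
                             (rs$points[, 2] - 50)^2) - 50)
  expect_lt(max(dev_from_arc), 0.5)
})

test_that("repeated resample-smooth application is stable", {
  v <- elbow_vessel(c(30, 50), c(40, 40, 40))
  r1 <- resample_smooth(v$cl, 1, 5)
  r2 <- resample_smooth(r1, 1, 5)
  expect_lt(max(abs(r1$points - r2$points)), 0.15)
  ## and the measurement it feeds is stable too
  a1 <- detect_curves(r1, prepare = FALSE)
  a2 <- detect_curves(resample_smooth(r1, 1, 5), prepare = FALSE)
  expect_equal(nrow(a1), nrow(a2))
  expect_lt(max(abs(a1$turn_angle - a2$turn_angle)), 0.5)
  ## exact fixed point on straight vessels
  s1 <- resample_smooth(straight_vessel(100), 1, 5)
  s2 <- resample_smooth(s1, 1, 5)
  expect_lt(max(abs(s1$points - s2$points)), 1e-9)
})

test_that("turning angle matches closed-form trigonometry", {
  straight <- centerline(rbind(c(0, 0, 0), c(10, 0, 0), c(20, 0, 0)), 7)
  expect_equal(turning_angle(straight, 2), 0)
  bend45 <- centerline(rbind(c(0, 0, 0), c(10, 0, 0), c(20, 10, 0)), 7)
  expect_equal(turning_angle(bend45, 2, offset = 10), 45, tolerance = 1e-9)
  bend90 <- centerline(rbind(c(0, 0, 0), c(10, 0, 0), c(10, 10, 0)), 7)
  expect_equal(turning_angle(bend90, 2, offset = 10), 90, tolerance = 1e-9)
  expect_error(turning_angle(bend90, 1, offset = 10), "boundary")
})

test_that("tortuosity measurements are invariant under rigid motion", {
  v <- elbow_vessel(c(25, 35, 55), c(30, 40, 40, 30), azimuths = c(0, 2, 4))
  p0 <- tortuosity_profile(v$cl)
  ## rotation about an arbitrary axis plus translation
  th <- 0.7; ax <- c(1, 2, 3) / sqrt(14)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  moved <- centerline(v$cl$points %*% t(R) +
                        matrix(c(12, -5, 80), nrow(v$cl$points), 3,
                               byrow = TRUE),
                      v$cl$sections$diameter)
  p1 <- tortuosity_profile(moved)
  for (f in c("n_curves", "sum_of_angles", "max_angle", "true_length",
              "ideal_length", "ift"))
    expect_equal(p1[[f]], p0[[f]], tolerance = 1e-6)
})

test_that("IFT is scale-free while lengths scale linearly", {
  v <- elbow_vessel(c(30, 40), c(40, 40, 40))
  p0 <- tortuosity_profile(v$cl)
  scaled <- centerline(2.5 * v$cl$points, v$cl$sections$diameter)
  p1 <- tortuosity_profile(scaled)
  expect_equal(p1$ift, p0$ift, tolerance = 1e-6)
  expect_equal(p1$true_length, 2.5 * p0$true_length, tolerance = 1e-6)
  expect_equal(p1$ideal_length, 2.5 * p0$ideal_length, tolerance = 1e-6)
})
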