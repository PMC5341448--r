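test_that("arc length matches hand geometry and is a rigid invariant", {
  cl <- centreline(rbind(c(0, 0, 0), c(3, 4, 0)))
  expect_equal(arc_length(cl), 5)

  cc <- aorta_curve("candy_cane", radius = 30, limb1 = 40, limb2 = 80)
  dense <- centreline(sample_curve(cc, 0.05))
  expect_equal(arc_length(dense), pi * 30 + 120, tolerance = 5e-4)

  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  rot <- centreline(dense$points %*% t(R))
  expect_equal(arc_length(rot), arc_length(dense), tolerance = 1e-9)
})

test_that("resampling is arithmetic-exact, idempotent and length-preserving", {
  line <- centreline(rbind(c(0, 0, 0), c(0, 0, 5)))
  rs <- resample_centreline(line, 0.1)
  expect_equal(nrow(rs$points), 51)
  expect_equal(arc_length(rs), 5)
  expect_equal(rs$points[1, ], c(0, 0, 0))
  expect_equal(rs$points[51, ], c(0, 0, 5))

  rs2 <- resample_centreline(rs, 0.1)
  expect_lt(max(abs(rs2$points - rs$points)), 1e-9)

  # quarter circle R = 30 sampled at 1 degree, resampled at 0.1 mm
  th <- seq(0, pi / 2, by = pi / 180)
  q <- centreline(cbind(30 * cos(th), 30 * sin(th), 0))
  qr <- resample_centreline(q, 0.1)
  expect_equal(arc_length(qr), 15 * pi, tolerance = 1e-4 * 15 * pi)
})

test_that("splitting at the descending landmark conserves length", {
  line <- resample_centreline(centreline(rbind(c(0, 0, 0), c(100, 0, 0))), 1)
  sp <- split_at_location(line, c(40.2, 3, 0))
  expect_equal(arc_length(sp$arch), 40)
  expect_equal(arc_length(sp$descending), 60)
  expect_equal(sp$arch$points[nrow(sp$arch$points), ],
               sp$descending$points[1, ])
  expect_equal(arc_length(sp$arch) + arc_length(sp$descending),
               arc_length(line), tolerance = 1e-6)

  # tie equidistant between 40 and 60 marks -> lower index wins
  sp2 <- split_at_location(line, c(50, 10, 0))
  expect_equal(arc_length(sp2$arch), 50)
  expect_error(split_at_location(line, c(-5, 0, 0)), "endpoint")
})

test_that("centreline distance is directional with exact simple cases", {
  a <- resample_centreline(centreline(rbind(c(0, 0, 0), c(50, 0, 0))), 0.5)
  expect_equal(max(centreline_distance(a, a)$distances), 0)

  b <- resample_centreline(centreline(rbind(c(0, 2, 0), c(50, 2, 0))), 0.5)
  d <- centreline_distance(a, b)$distances
  expect_equal(unname(range(d)), c(2, 2))

  # short sub-segment vs full line: zero one way, positive the other
  sub <- resample_centreline(centreline(rbind(c(10, 0, 0), c(20, 0, 0))), 0.5)
  expect_equal(centreline_distance(sub, a)$summary$mean, 0, tolerance = 1e-9)
  expect_gt(centreline_distance(a, sub)$summary$mean, 1)

  # brute-force oracle on small random polylines
  set.seed(5)
  p1 <- matrix(runif(30, 0, 10), ncol = 3)
  p2 <- matrix(runif(24, 0, 10), ncol = 3)
  got <- centreline_distance(centreline(p1), centreline(p2))$distances
  brute <- apply(p1, 1, function(r)
    min(sqrt(colSums((t(p2) - r)^2))))
  expect_equal(unname(got), unname(brute))
})

test_that("ray-cast ellipse fitting re-centres displaced seeds", {
  vol <- cylinder_volume(radius = 15)
  axis_pt <- c(39.5, 39.5, 20)
  off <- axis_pt + c(2, -1, 0)
  rec <- recenter_seed(vol, off, axis_hint = c(0, 0, 1), search_radius = 25)
  expect_lt(sqrt(sum((rec[1:2] - axis_pt[1:2])^2)), 0.5)
  expect_equal(rec[3], off[3])  # correction stays in the normal plane

  on_axis <- recenter_seed(vol, axis_pt, axis_hint = c(0, 0, 1),
                           search_radius = 25)
  expect_lt(sqrt(sum((on_axis - axis_pt)^2)), 0.25)

  flat <- volume_image(array(5, c(32, 32, 32)))
  expect_error(recenter_seed(flat, c(15, 15, 15), c(0, 0, 1)), "edge")
})

test_that("the open active contour straightens a zigzag onto the axis", {
  tube <- small_tube("bright")
  axis_xy <- c(31.5, 31.5)
  z <- seq(15, 49, by = 1)
  zig <- cbind(axis_xy[1] + rep(c(2, -2), length.out = length(z)),
               axis_xy[2], z)
  zig[1, 1] <- axis_xy[1]
  zig[nrow(zig), 1] <- axis_xy[1]
  out <- refine_active_contour(zig, tube$volume, trace = TRUE,
                               decimate = FALSE)
  p <- out$points
  expect_equal(p[1, ], zig[1, ], tolerance = 1e-12)
  expect_equal(p[nrow(p), ], zig[nrow(zig), ], tolerance = 1e-12)
  rms <- sqrt(mean(rowSums(sweep(p[, 1:2, drop = FALSE], 2, axis_xy)^2)))
  expect_lt(rms, 0.5)
  # distance to axis is non-increasing across iterations (up to the
  # convergence tolerance of the centring estimate)
  tr <- attr(out, "trace")
  rms_it <- vapply(tr, function(q)
    sqrt(mean(rowSums(sweep(q[, 1:2, drop = FALSE], 2, axis_xy)^2))),
    numeric(1))
  expect_true(all(diff(c(sqrt(mean(rowSums(
    sweep(zig[, 1:2, drop = FALSE], 2, axis_xy)^2))), rms_it)) <= 0.01))
})

test_that("a chain on the tube axis is a fixed point of refinement", {
  tube <- small_tube("bright")
  z <- seq(15, 49, by = 1)
  chain <- cbind(31.5, 31.5, z)
  out <- refine_active_contour(chain, tube$volume, decimate = FALSE)
  expect_lt(max(sqrt(rowSums((out$points - chain)^2))), 0.1)
})
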