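test_that("plane fitting is exact for planar curves and rejects collinear ones", {
  th <- seq(0, pi, length.out = 50)
  cshape <- cbind(30 * cos(th), 30 * sin(th), 0) %*%
    rbind(c(1, 0, 0), c(0, cos(0.4), sin(0.4)), c(0, -sin(0.4), cos(0.4)))
  cl <- centreline(cshape)
  pl <- fit_oblique_sagittal(cl)
  res <- abs(sweep(cl$points, 2, pl$point) %*% pl$normal)
  expect_lt(max(res), 1e-9)
  expect_gte(pl$normal[1], 0)

  # order reversal leaves the plane unchanged (up to the orientation rule)
  pl2 <- fit_oblique_sagittal(centreline(cshape[nrow(cshape):1, ]))
  expect_equal(abs(sum(pl2$normal * pl$normal)), 1, tolerance = 1e-9)

  line <- centreline(cbind(1:10, 2 * (1:10), 3 * (1:10)))
  expect_error(fit_oblique_sagittal(line), "collinear")

  # out-of-plane bulge produces a nonzero residual (sin(2 theta) is not
  # linear in the in-plane coordinates, so no tilted plane can absorb it)
  bulge <- cshape
  bulge[, 3] <- bulge[, 3] + 10 * sin(2 * th)
  plb <- fit_oblique_sagittal(centreline(bulge))
  resb <- abs(sweep(bulge, 2, plb$point) %*% plb$normal)
  expect_gt(max(resb), 1)
})

test_that("projection never lengthens a curve; helix case matches closed form", {
  # helix projected along its axis -> circle
  hel <- aorta_curve("helix", radius = 20, pitch = 30, turns = 1)
  pts <- sample_curve(hel, 0.05)
  cl <- centreline(pts)
  axis_plane <- plane_def(c(0, 0, 0), c(0, 0, 1))
  p2 <- project_to_plane(cl, axis_plane)
  expect_equal(arc_length_2d(p2), 2 * pi * 20, tolerance = 1e-3 * 2 * pi * 20)
  expect_equal(arc_length(cl), 2 * pi * sqrt(20^2 + (30 / (2 * pi))^2),
               tolerance = 1e-4)
  expect_lt(arc_length_2d(p2), arc_length(cl))

  # in-plane curve projects without loss
  th <- seq(0, pi, length.out = 100)
  flat <- centreline(cbind(30 * cos(th), 30 * sin(th), 5))
  pf <- project_to_plane(flat, axis_plane)
  expect_equal(arc_length_2d(pf), arc_length(flat), tolerance = 1e-9)

  # property: 100 random smooth curves, random planes
  set.seed(11)
  for (i in 1:100) {
    crv <- random_curve_points(planar = FALSE)
    nrm <- rnorm(3)
    pl <- plane_def(rnorm(3), nrm)
    l2 <- arc_length_2d(project_to_plane(centreline(crv), pl))
    l3 <- arc_length(crv)
    expect_lte(l2, l3 + 1e-9)
    expect_lt(l2, l3)  # non-planar curves project strictly shorter
  }
})

test_that("flow-plane marks clip a 2D centreline at the expected length", {
  meas <- plane_def(c(0, 0, 0), c(0, 0, 1),
                    in_plane_axes = rbind(c(1, 0, 0), c(0, 1, 0)))
  f1 <- plane_def(c(10, 0, 0), c(1, 0, 0))
  f2 <- plane_def(c(30, 0, 0), c(1, 0, 0))
  m1 <- flow_plane_marks(meas, f1)
  m2 <- flow_plane_marks(meas, f2)
  # orthogonal planes through a common point intersect along the shared axis
  expect_equal(abs(m1$direction), c(0, 1), tolerance = 1e-12)

  line <- centreline(cbind(seq(0, 50, by = 0.5), 3, 0))
  p2 <- project_to_plane(line, meas)
  clipped <- clip_at_marks(p2, m1, m2)
  expect_equal(arc_length_2d(clipped), 20, tolerance = 1e-9)

  expect_error(flow_plane_marks(meas, plane_def(c(0, 0, 9), c(0, 0, 1))),
               "parallel")
})

test_that("rigid motion changes clipped 2D length but not 3D arc length", {
  cc <- aorta_curve("candy_cane", base = c(0, 0, 0), radius = 25,
                    limb1 = 30, limb2 = 50)
  cl <- centreline(sample_curve(cc, 0.2))
  meas <- plane_def(c(0, 0, 0), c(0, 1, 0),
                    in_plane_axes = rbind(c(1, 0, 0), c(0, 0, 1)))
  # one mark crosses the ascending limb, the other only the (longer)
  # descending limb, as the ASC and DIAPH flow planes do
  fstart <- plane_def(c(0, 0, 25), c(0, 0, 1))
  fend <- plane_def(c(50, 0, -10), c(0, 0, 1))
  m1 <- flow_plane_marks(meas, fstart)
  m2 <- flow_plane_marks(meas, fend)
  clip0 <- arc_length_2d(clip_at_marks(project_to_plane(cl, meas), m1, m2))

  # identity transform: nothing changes
  ident <- simulate_motion(cl)
  expect_equal(ident$points, cl$points, tolerance = 1e-12)

  moved <- simulate_motion(cl, translation = c(0, 0, 4))  # along flow normals
  expect_equal(arc_length(moved), arc_length(cl), tolerance = 1e-9)
  clip1 <- arc_length_2d(clip_at_marks(project_to_plane(moved, meas), m1, m2))
  expect_gt(abs(clip1 - clip0), 0.5)

  th <- 0
  rot0 <- simulate_motion(cl, rotation = diag(3))
  expect_equal(rot0$points, cl$points, tolerance = 1e-12)
  expect_error(simulate_motion(cl, rotation = matrix(1, 3, 3)), "orthonormal")
})
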