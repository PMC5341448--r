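test_that("constant images have identically zero Hessian eigenvalues", {
  vol <- volume_image(array(7, c(24, 24, 24)))
  ev <- hessian_eigenvalues(vol, 2)
  expect_equal(max(abs(ev$l1)), 0)
  expect_equal(max(abs(ev$l3)), 0)
})

test_that("Gaussian blob eigenvalues match the closed-form second derivative", {
  # image exp(-r^2 / 2 sb^2); smoothing at ss gives amplitude
  # (sb^2/sc^2)^(3/2) and curvature -1/sc^2 per axis at the centre, with
  # sc^2 = sb^2 + ss^2; gamma-normalisation multiplies by ss^2
  n <- 65; sb <- 6; ss <- 4
  ax <- seq_len(n) - 1 - 32
  r2 <- outer(outer(ax^2, ax^2, `+`), ax^2, `+`)
  vol <- volume_image(array(exp(-r2 / (2 * sb^2)), c(n, n, n)))
  ev <- hessian_eigenvalues(vol, ss)
  sc2 <- sb^2 + ss^2
  expected <- -ss^2 * (sb^2 / sc2)^1.5 / sc2
  for (l in ev)
    expect_equal(l[33, 33, 33], expected, tolerance = 0.02)
})

test_that("a bright tube has one near-zero and two negative eigenvalues on axis", {
  tube <- small_tube("bright")
  ev <- hessian_eigenvalues(tube$volume, 4)
  mid <- round(drop(tube$curve$point_at(19))) + 1
  l1 <- ev$l1[mid[1], mid[2], mid[3]]
  l2 <- ev$l2[mid[1], mid[2], mid[3]]
  l3 <- ev$l3[mid[1], mid[2], mid[3]]
  expect_lt(abs(l1), 0.1 * abs(l2))
  expect_lt(l2, 0)
  expect_lt(l3, 0)
  expect_equal(l2, l3, tolerance = 0.15)
})

test_that("single-voxel tubularity matches the closed-form expression", {
  # lambda = (0, -a, -a) with a >> c: RA = 1, RB = 0, S ~ a sqrt(2)
  a <- 10
  eig <- list(l1 = array(0, c(1, 1, 1)), l2 = array(-a, c(1, 1, 1)),
              l3 = array(-a, c(1, 1, 1)))
  pars <- vesselness_params(alpha = 0.5, beta = 0.5, c = 1,
                            polarity = "bright")
  v <- frangi_response(eig, pars)
  hand <- (1 - exp(-1 / (2 * 0.5^2))) * 1 *
    (1 - exp(-(2 * a^2) / (2 * 1^2)))
  expect_equal(v[1, 1, 1], hand, tolerance = 1e-12)

  # sign gate: positive eigenvalues kill the bright response
  eigpos <- list(l1 = array(0, c(1, 1, 1)), l2 = array(1, c(1, 1, 1)),
                 l3 = array(2, c(1, 1, 1)))
  expect_equal(frangi_response(eigpos, pars)[1, 1, 1], 0)
})

test_that("dark-lumen response on an inverted volume equals the bright response", {
  tube <- small_tube("bright")
  inv <- volume_image(200 - tube$volume$data, spacing = tube$volume$spacing,
                      origin = tube$volume$origin)
  vb <- multiscale_vesselness(tube$volume, c(4, 6),
                              vesselness_params(polarity = "bright"))
  vd <- multiscale_vesselness(inv, c(4, 6),
                              vesselness_params(polarity = "dark"))
  expect_lt(max(abs(vb$response - vd$response)), 1e-6)
})

test_that("multi-scale response is the pointwise max over scales", {
  tube <- small_tube("bright")
  pars <- vesselness_params(polarity = "bright")
  single <- multiscale_vesselness(tube$volume, 4, pars)
  direct <- frangi_response(hessian_eigenvalues(tube$volume, 4), pars)
  expect_equal(single$response, direct)

  both <- multiscale_vesselness(tube$volume, c(4, 6), pars)
  expect_true(all(both$response >= single$response - 1e-12))
  expect_true(all(both$response >= 0 & both$response <= 1))
  expect_true(all(both$argmax_scale %in% c(4, 6)))
})

test_that("tube response peaks on the axis and dwarfs the background", {
  tube <- small_tube("bright")
  v <- multiscale_vesselness(tube$volume, c(4, 6),
                             vesselness_params(polarity = "bright"))
  mid <- round(drop(tube$curve$point_at(19))) + 1
  on_axis <- v$response[mid[1], mid[2], mid[3]]
  edge <- v$response[mid[1] + 6, mid[2], mid[3]]
  bg <- stats::median(v$response[1:10, 1:10, ])
  expect_gt(on_axis, edge)
  expect_gt(on_axis, 5 * max(bg, 1e-6))
})

test_that("axis-aligned 90-degree rotation commutes with the filter", {
  tube <- small_tube("bright")
  rot <- function(a) aperm(a[, dim(a)[2]:1, ], c(2, 1, 3))  # 90 deg about z
  vol_r <- volume_image(rot(tube$volume$data))
  pars <- vesselness_params(polarity = "bright")
  v <- multiscale_vesselness(tube$volume, 4, pars)
  v_r <- multiscale_vesselness(vol_r, 4, pars)
  expect_lt(max(abs(v_r$response - rot(v$response))), 1e-10)
})

test_that("sub-spacing scales warn and non-finite volumes error", {
  tube <- small_tube("bright")
  expect_warning(hessian_eigenvalues(tube$volume, 0.5), "spacing")
  expect_error(multiscale_vesselness(tube$volume, c(6, 4)), "increasing")
})
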