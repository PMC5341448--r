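test_that("ray-cast circle fitting recovers a synthetic disk to sub-pixel", {
  st <- make_pc_stack(lumen_radius = 15, centre = c(32, 32),
                      peak_velocity = rep(800, 4), frame_dim = c(64, 64))
  fit <- fit_lumen_circle(st$magnitude[, , 1], seed = c(32, 32),
                          search_radius = 25)
  expect_lt(sqrt(sum((fit$centre - c(32, 32))^2)), 0.25)
  expect_lt(abs(fit$radius - 15), 0.5)

  # off-centre seed: one re-seeding iteration at the fitted centre recovers
  # the same circle
  f1 <- fit_lumen_circle(st$magnitude[, , 1], seed = c(35, 29),
                         search_radius = 25)
  f2 <- fit_lumen_circle(st$magnitude[, , 1], seed = f1$centre,
                         search_radius = 25)
  expect_lt(sqrt(sum((f2$centre - c(32, 32))^2)), 0.25)
  expect_lt(abs(f2$radius - 15), 0.5)

  expect_error(fit_lumen_circle(matrix(7, 64, 64), seed = c(32, 32)),
               "edge")
})

test_that("segmentation propagates across phases, tracking the lumen", {
  st <- make_pc_stack(lumen_radius = 15, centre = c(32, 32),
                      peak_velocity = rep(800, 5), frame_dim = c(64, 64))
  circles <- propagate_segmentation(st$magnitude, c(32, 32),
                                    search_radius = 25)
  expect_length(circles, 5)
  centres <- t(vapply(circles, `[[`, numeric(2), "centre"))
  expect_lt(max(abs(sweep(centres, 2, c(32, 32)))), 0.25)

  # pulsating radius tracked within half a pixel
  radii <- c(12, 13, 14.5, 14, 13)
  frames <- array(0, dim = c(64, 64, 5))
  for (k in 1:5)
    frames[, , k] <- make_pc_stack(lumen_radius = radii[k],
                                   centre = c(32, 32),
                                   peak_velocity = 1,
                                   frame_dim = c(64, 64))$magnitude[, , 1]
  circ <- propagate_segmentation(frames, c(32, 32), search_radius = 25)
  got <- vapply(circ, `[[`, numeric(1), "radius")
  expect_lt(max(abs(got - radii)), 0.5)

  # single phase equals a direct fit
  single <- propagate_segmentation(st$magnitude[, , 1, drop = FALSE],
                                   c(32, 32), search_radius = 25)
  direct <- fit_lumen_circle(st$magnitude[, , 1], c(32, 32),
                             search_radius = 25)
  expect_equal(single[[1]]$centre, direct$centre)

  blank <- array(5, dim = c(32, 32, 3))
  expect_error(propagate_segmentation(blank, c(16, 16)), "phase 1")
})

test_that("waveform extraction integrates the parabolic profile", {
  peaks <- c(200, 800, 1500, 400)
  st <- make_pc_stack(lumen_radius = 15, centre = c(32, 32),
                      peak_velocity = peaks, frame_dim = c(64, 64))
  circles <- propagate_segmentation(st$magnitude, c(32, 32),
                                    search_radius = 25)
  # 8 phases minimum for a waveform: reuse times of a longer series
  circles8 <- c(circles, circles)
  vel8 <- array(0, dim = c(64, 64, 8))
  vel8[, , 1:4] <- st$velocity
  vel8[, , 5:8] <- st$velocity
  w <- extract_waveform(vel8, circles8, pixel_size = 1,
                        times = seq(0, by = 8.4, length.out = 8))
  analytic <- rep(peaks, 2) * pi * 15^2 / 2 / 1000
  expect_equal(w$flow, analytic, tolerance = 0.02)

  # linearity: doubling velocity doubles flow
  w2 <- extract_waveform(2 * vel8, circles8, pixel_size = 1,
                         times = seq(0, by = 8.4, length.out = 8))
  expect_equal(w2$flow, 2 * w$flow, tolerance = 1e-9)

  zero <- extract_waveform(0 * vel8, circles8, pixel_size = 1,
                           times = seq(0, by = 8.4, length.out = 8))
  expect_true(all(zero$flow == 0))
})

test_that("foot-to-foot recovers known delays at clinical sampling", {
  for (d in c(5, 10, 20, 40)) {
    pr <- make_flow_pair(waveform_spec(foot_time = 100),
                         waveform_spec(foot_time = 100 + d))
    est <- as.numeric(foot_to_foot(pr$w1, pr$w2))
    expect_lt(abs(est - d), 1)
  }

  # identity and antisymmetry
  w <- synth_waveform(waveform_spec(foot_time = 120))
  expect_equal(as.numeric(foot_to_foot(w, w)), 0, tolerance = 1e-9)
  pr <- make_flow_pair(waveform_spec(foot_time = 100),
                       waveform_spec(foot_time = 113))
  expect_equal(as.numeric(foot_to_foot(pr$w1, pr$w2)),
               -as.numeric(foot_to_foot(pr$w2, pr$w1)), tolerance = 1e-9)

  flat <- flow_waveform(seq(0, 70, by = 10), rep(3, 8))
  expect_error(waveform_foot(flat), "upstroke")
  falling <- flow_waveform(seq(0, 70, by = 10), seq(8, 1))
  expect_error(waveform_foot(falling), "upstroke")
})

test_that("PWV is length over transit time with unit-safe errors", {
  p <- compute_pwv(100, 20, "ASC-DIAPH")
  expect_equal(p$pwv_m_per_s, 5)
  p2 <- compute_pwv(214.248, 35, "ASC-DIAPH")
  expect_equal(p2$pwv_m_per_s, 6.121, tolerance = 1e-4)
  expect_error(compute_pwv(100, 0), "transit")
  expect_error(compute_pwv(100, -3), "transit")
  expect_error(compute_pwv(0, 10), "length")
})
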