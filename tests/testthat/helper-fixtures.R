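# Shared fixtures, computed once per test session and cached.

.fixtures <- new.env(parent = emptyenv())

cached_fixture <- function(key, expr) {
  if (!exists(key, envir = .fixtures, inherits = FALSE))
    assign(key, force(expr), envir = .fixtures)
  get(key, envir = .fixtures, inherits = FALSE)
}

# Full-size phantom cell (128^3, 1 mm, scales {4,6}) tracked end to end.
tracked_cell <- function(geometry, polarity, dropout = FALSE) {
  key <- paste("cell", geometry, polarity, dropout, sep = "_")
  cached_fixture(key, {
    fx <- phantom_fixture(geometry, polarity, dropout = dropout)
    cfg <- run_config(polarity = polarity)
    res <- tryCatch(
      track_centreline(fx$volume, fx$seed_start, fx$seed_end, cfg,
                       axis_hint_start = fx$axis_hint_start,
                       axis_hint_end = fx$axis_hint_end),
      error = function(e) e)
    list(fx = fx, res = res, config = cfg)
  })
}

# Small straight bright tube (64^3) for filter-level tests: radius 6 mm
# along z, centred in x/y.
small_tube <- function(polarity = "bright", noise = 0) {
  key <- paste("tube64", polarity, noise, sep = "_")
  cached_fixture(key, {
    curve <- aorta_curve("straight", start = c(31.5, 31.5, 13),
                         direction = c(0, 0, 1), length = 38)
    lum <- if (polarity == "bright") c(100, 10) else c(10, 100)
    spec <- tube_spec(curve, lumen_radius = 6, lumen_intensity = lum[1],
                      background_intensity = lum[2], blur_sigma = 1,
                      noise_sigma = noise, seed = 7L)
    ph <- make_tube_phantom(spec, grid_dim = c(64, 64, 64))
    c(ph, list(curve = curve))
  })
}

# Analytic (noise-free, unblurred-edge) cylinder volume built directly from
# the distance to an axis; used for ray-cast fitting tests where the tube
# radius must exceed what make_tube_phantom's margin rule allows.
cylinder_volume <- function(radius = 15, dim = c(80, 80, 40),
                            centre = c(39.5, 39.5), blur = 1) {
  key <- paste("cyl", radius, paste(dim, collapse = "x"), blur, sep = "_")
  cached_fixture(key, {
    r2 <- outer((seq_len(dim[1]) - 1 - centre[1])^2,
                (seq_len(dim[2]) - 1 - centre[2])^2, `+`)
    sl <- ifelse(r2 < radius^2, 100, 10)
    arr <- array(rep(sl, dim[3]), dim = dim)
    if (blur > 0) arr <- gaussian_blur(arr, blur)
    volume_image(arr)
  })
}

# Smooth random 3D curve for projection property tests.
random_curve_points <- function(n = 60, planar = FALSE) {
  t <- seq(0, 1, length.out = n)
  coef <- matrix(stats::rnorm(9), 3, 3)
  x <- coef[1, 1] * sin(2 * pi * t) + coef[1, 2] * cos(4 * pi * t) +
    coef[1, 3] * t
  y <- coef[2, 1] * sin(4 * pi * t) + coef[2, 2] * cos(2 * pi * t) +
    coef[2, 3] * t
  z <- if (planar) rep(0, n) else
    coef[3, 1] * sin(6 * pi * t) + coef[3, 2] * t^2 + coef[3, 3] * t
  cbind(x, y, z) * 20
}

expect_no_failure <- function(cell) {
  expect_false(inherits(cell$res, "error"),
               info = if (inherits(cell$res, "error"))
                 conditionMessage(cell$res) else NULL)
}
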