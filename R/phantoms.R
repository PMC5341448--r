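#' Analytic vessel curves
#'
#' Parametric 3D curves with closed-form arc length, used as ground-truth
#' centrelines for tube phantoms. Supported shapes: a straight segment, a
#' circular arc, a "candy-cane" (straight limb, half-ish arc, straight limb,
#' tangent-continuous — the idealised thoracic aorta), and a circular helix.
#' All curves are parameterised by arc length `s` in `[0, length]`.
#'
#' @param kind One of `"straight"`, `"arc"`, `"candy_cane"`, `"helix"`.
#' @param start Start point (mm), `"straight"` only.
#' @param direction Direction vector, `"straight"` only.
#' @param length Segment length in mm, `"straight"` only.
#' @param centre Arc/helix centre (mm).
#' @param radius Arc/helix radius in mm.
#' @param u,v Orthonormal in-plane basis of the arc plane.
#' @param theta0 Arc start angle (radians) in the (u, v) basis.
#' @param span Arc angular span in radians (positive).
#' @param base Candy-cane: start of the first limb (mm).
#' @param limb1,limb2 Candy-cane limb lengths in mm.
#' @param axis Helix axis direction.
#' @param pitch Helix pitch (mm of axial travel per full turn).
#' @param turns Helix number of turns (may be fractional).
#' @return An object of class `aorta_curve` with fields `point_at(s)`
#'   (vectorised), `length` (closed form, mm) and `kind`.
#' @export
aorta_curve <- function(kind = c("straight", "arc", "candy_cane", "helix"),
                        start = c(0, 0, 0), direction = c(0, 0, 1),
                        length = 100,
                        centre = c(0, 0, 0), radius = 30,
                        u = c(1, 0, 0), v = c(0, 0, 1),
                        theta0 = pi, span = pi,
                        base = c(0, 0, 0), limb1 = 30, limb2 = 50,
                        axis = c(0, 0, 1), pitch = 30, turns = 1) {
  kind <- match.arg(kind)
  cv <- switch(kind,
    straight = {
      stopifnot(length > 0)
      d <- .unit(direction)
      list(point_at = function(s) {
        cbind(start[1] + s * d[1], start[2] + s * d[2], start[3] + s * d[3])
      }, length = length)
    },
    arc = {
      stopifnot(radius > 0, span > 0)
      uu <- .unit(u)
      vv <- .unit(v - sum(v * uu) * uu)
      list(point_at = function(s) {
        th <- theta0 + s / radius
        cbind(centre[1] + radius * (cos(th) * uu[1] + sin(th) * vv[1]),
              centre[2] + radius * (cos(th) * uu[2] + sin(th) * vv[2]),
              centre[3] + radius * (cos(th) * uu[3] + sin(th) * vv[3]))
      }, length = radius * span)
    },
    candy_cane = {
      # limb1 rises along +z from `base`, a half circle of given radius in
      # the x-z plane crosses the top, limb2 descends along -z.
      stopifnot(radius > 0, limb1 > 0, limb2 > 0)
      ltot <- limb1 + pi * radius + limb2
      a <- base + c(0, 0, limb1)           # end of limb 1
      cen <- a + c(radius, 0, 0)           # arc centre
      b <- a + c(2 * radius, 0, 0)         # start of limb 2 (descending)
      list(point_at = function(s) {
        out <- matrix(0, nrow = base::length(s), ncol = 3)
        i1 <- s <= limb1
        i2 <- s > limb1 & s <= limb1 + pi * radius
        i3 <- s > limb1 + pi * radius
        if (any(i1))
          out[i1, ] <- cbind(base[1], base[2], base[3] + s[i1])
        if (any(i2)) {
          th <- pi - (s[i2] - limb1) / radius   # pi -> 0 over the top
          out[i2, ] <- cbind(cen[1] + radius * cos(th), cen[2],
                             cen[3] + radius * sin(th))
        }
        if (any(i3)) {
          ds <- s[i3] - limb1 - pi * radius
          out[i3, ] <- cbind(b[1], b[2], b[3] - ds)
        }
        out
      }, length = ltot)
    },
    helix = {
      stopifnot(radius > 0, turns > 0)
      w <- .unit(axis)
      ref <- if (abs(w[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      uu <- .unit(ref - sum(ref * w) * w)
      vv <- .cross3(w, uu)
      cpar <- pitch / (2 * pi)               # axial rise per radian
      k <- sqrt(radius^2 + cpar^2)           # ds/dtheta
      ltot <- 2 * pi * turns * k
      list(point_at = function(s) {
        th <- s / k
        cbind(centre[1] + radius * (cos(th) * uu[1] + sin(th) * vv[1]) + cpar * th * w[1],
              centre[2] + radius * (cos(th) * uu[2] + sin(th) * vv[2]) + cpar * th * w[2],
              centre[3] + radius * (cos(th) * uu[3] + sin(th) * vv[3]) + cpar * th * w[3])
      }, length = ltot)
    })
  structure(list(point_at = cv$point_at, length = cv$length, kind = kind),
            class = "aorta_curve")
}

#' Sample an analytic curve at uniform arc-length spacing
#'
#' @param curve An [aorta_curve].
#' @param spacing Arc-length sample spacing in mm (<= 0.1 recommended for
#'   ground truth).
#' @return n x 3 matrix of points; the exact endpoint is always included.
#' @export
sample_curve <- function(curve, spacing = 0.1) {
  s <- seq(0, curve$length, by = spacing)
  if (curve$length - s[length(s)] > 1e-9) s <- c(s, curve$length)
  curve$point_at(s)
}

#' Tube phantom specification
#'
#' Describes a synthetic vessel: an analytic centreline curve, a lumen of
#' constant radius, lumen/background intensities (bright- or dark-lumen),
#' Gaussian blur and noise, and an optional signal-dropout window that
#' attenuates the lumen over an arc-length interval (emulating the
#' bright-blood arch dropout failure mode).
#'
#' @param curve An [aorta_curve].
#' @param lumen_radius Lumen radius in mm (> 0).
#' @param lumen_intensity,background_intensity Intensities (a.u.).
#' @param blur_sigma Gaussian blur in mm applied after voxelisation.
#' @param noise_sigma Additive Gaussian noise SD (intensity units).
#' @param dropout `NULL`, or `list(position =, extent =, attenuation =)`:
#'   arc-length centre (mm), window width (mm) and a factor in `[0, 1]`
#'   multiplying the lumen-background contrast inside the window.
#' @param seed RNG seed for the noise (phantoms are deterministic given it).
#' @return An object of class `tube_spec`.
#' @export
tube_spec <- function(curve, lumen_radius = 6, lumen_intensity = 100,
                      background_intensity = 10, blur_sigma = 1,
                      noise_sigma = 2, dropout = NULL, seed = 1L) {
  stopifnot(inherits(curve, "aorta_curve"), lumen_radius > 0,
            blur_sigma >= 0, noise_sigma >= 0)
  if (lumen_intensity == background_intensity)
    stop("lumen and background intensities must differ")
  if (!is.null(dropout)) {
    stopifnot(is.list(dropout),
              all(c("position", "extent", "attenuation") %in% names(dropout)),
              dropout$extent > 0, dropout$attenuation >= 0,
              dropout$attenuation <= 1)
  }
  structure(list(curve = curve, lumen_radius = lumen_radius,
                 lumen_intensity = lumen_intensity,
                 background_intensity = background_intensity,
                 polarity = if (lumen_intensity > background_intensity)
                   "bright" else "dark",
                 blur_sigma = blur_sigma, noise_sigma = noise_sigma,
                 dropout = dropout, seed = as.integer(seed)),
            class = "tube_spec")
}

#' Generate a tube phantom volume with its analytic ground-truth centreline
#'
#' Voxels closer to the curve than `lumen_radius` get the lumen intensity,
#' all others the background intensity; the volume is then Gaussian-blurred
#' and seeded Gaussian noise is added. The returned ground truth is the
#' analytic curve sampled at 0.1 mm with its closed-form length attached as
#' attribute `"analytic_length"`.
#'
#' @param spec A [tube_spec].
#' @param grid_dim Length-3 integer grid size (voxels); default `c(128,128,128)`.
#' @param spacing Voxel spacing in mm; default 1 mm isotropic.
#' @param origin World position of voxel (0,0,0); default `c(0,0,0)`.
#' @return `list(volume = volume_image, truth = centreline)`.
#' @export
make_tube_phantom <- function(spec, grid_dim = c(128, 128, 128),
                              spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  stopifnot(inherits(spec, "tube_spec"))
  grid_dim <- as.integer(grid_dim)
  r <- spec$lumen_radius
  step <- min(0.25, r / 4)
  s <- seq(0, spec$curve$length, by = step)
  if (spec$curve$length - s[length(s)] > 1e-9) s <- c(s, spec$curve$length)
  pts <- spec$curve$point_at(s)
  # margin check: tube (curve +/- lumen radius) must stay >= 2r from the
  # grid boundary
  lo <- origin
  hi <- origin + (grid_dim - 1) * spacing
  margin <- 2 * r
  if (any(sweep(pts, 2, lo + margin, `<`)) ||
      any(sweep(pts, 2, hi - margin, `>`)))
    stop("tube exits the grid: the curve must keep a margin of ",
         "2 * lumen_radius from the volume boundary")

  vol <- array(spec$background_intensity, dim = grid_dim)
  # paint spheres along the densely sampled curve (union ~ distance < r)
  rv <- ceiling(r / spacing)
  off <- as.matrix(expand.grid(x = -rv[1]:rv[1], y = -rv[2]:rv[2],
                               z = -rv[3]:rv[3]))
  offw <- sweep(off, 2, spacing, `*`)
  keep <- rowSums(offw^2) <= (r + max(spacing))^2  # candidate shell
  off <- off[keep, , drop = FALSE]
  offw <- offw[keep, , drop = FALSE]

  paint <- function(sample_idx, value) {
    for (i in sample_idx) {
      ci <- round((pts[i, ] - origin) / spacing)
      cand <- sweep(off, 2, ci, `+`)
      inside <- rowSums(sweep(sweep(cand, 2, spacing, `*`),
                              2, pts[i, ] - origin, `-`)^2) < r^2
      cand <- cand[inside, , drop = FALSE]
      ok <- cand[, 1] >= 0 & cand[, 1] < grid_dim[1] &
            cand[, 2] >= 0 & cand[, 2] < grid_dim[2] &
            cand[, 3] >= 0 & cand[, 3] < grid_dim[3]
      cand <- cand[ok, , drop = FALSE] + 1L
      vol[cand] <<- value
    }
  }
  paint(seq_along(s), spec$lumen_intensity)
  if (!is.null(spec$dropout)) {
    win <- abs(s - spec$dropout$position) <= spec$dropout$extent / 2
    att <- spec$background_intensity + spec$dropout$attenuation *
      (spec$lumen_intensity - spec$background_intensity)
    paint(which(win), att)
  }

  if (spec$blur_sigma > 0)
    vol <- gaussian_blur(vol, spec$blur_sigma / spacing)
  if (spec$noise_sigma > 0)
    vol <- vol + .with_seed(spec$seed,
                            array(stats::rnorm(prod(grid_dim),
                                               sd = spec$noise_sigma),
                                  dim = grid_dim))

  truth <- centreline(sample_curve(spec$curve, 0.1), label = spec$curve$kind)
  attr(truth, "analytic_length") <- spec$curve$length
  list(volume = volume_image(vol, spacing = spacing, origin = origin),
       truth = truth)
}

#' Flow-waveform specification
#'
#' The synthetic waveform is a flat baseline, a smooth sigmoidal systolic
#' upstroke, and an exponential diastolic decay. The sigmoid is constructed
#' so that the tangent at its maximum gradient intersects the baseline
#' exactly at `foot_time`, giving the foot-to-foot estimator an analytic
#' oracle.
#'
#' @param baseline Baseline flow in ml/s.
#' @param peak Peak flow in ml/s (> baseline).
#' @param foot_time Analytic foot of the upstroke in ms, in `[0, duration)`.
#' @param upstroke_duration Rise duration in ms (> 0); the sigmoid time
#'   constant is `upstroke_duration / 4`.
#' @param decay_tau Exponential decay constant in ms.
#' @param sampling Sampling interval in ms (default 8.4, a typical
#'   phase-contrast temporal resolution).
#' @param duration Waveform duration in ms.
#' @param noise_sigma Additive Gaussian noise SD in ml/s.
#' @param seed RNG seed for the noise.
#' @return An object of class `waveform_spec`.
#' @export
waveform_spec <- function(baseline = 5, peak = 400, foot_time = 100,
                          upstroke_duration = 60, decay_tau = 150,
                          sampling = 8.4, duration = 800, noise_sigma = 0,
                          seed = 1L) {
  stopifnot(upstroke_duration > 0, sampling > 0, duration > 0,
            decay_tau > 0, peak > baseline, noise_sigma >= 0)
  if (foot_time < 0 || foot_time >= duration)
    stop("foot_time must lie within [0, duration)")
  structure(list(baseline = baseline, peak = peak, foot_time = foot_time,
                 upstroke_duration = upstroke_duration,
                 decay_tau = decay_tau, sampling = sampling,
                 duration = duration, noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "waveform_spec")
}

# Continuous-time synthetic waveform; exported for oracle computations.
#' Evaluate a synthetic waveform in continuous time
#' @param spec A [waveform_spec].
#' @param t Times in ms.
#' @return Flow in ml/s (noise-free).
#' @export
waveform_value <- function(spec, t) {
  tau <- spec$upstroke_duration / 4
  t0 <- spec$foot_time + 2 * tau      # max-gradient time; tangent foot exact
  amp <- spec$peak - spec$baseline
  s <- 1 / (1 + exp(-(t - t0) / tau))
  tpk <- t0 + 4 * tau                 # decay starts once the rise saturates
  dec <- ifelse(t > tpk, exp(-(t - tpk) / spec$decay_tau), 1)
  spec$baseline + amp * s * dec
}

#' Generate a sampled flow waveform from a specification
#' @param spec A [waveform_spec].
#' @param location Label: `"ASC"`, `"DESC"` or `"DIAPH"`.
#' @return A [flow_waveform].
#' @export
synth_waveform <- function(spec, location = "ASC") {
  t <- seq(0, spec$duration, by = spec$sampling)
  f <- waveform_value(spec, t)
  if (spec$noise_sigma > 0)
    f <- f + .with_seed(spec$seed, stats::rnorm(length(t),
                                                sd = spec$noise_sigma))
  flow_waveform(t, f, location = location)
}

#' Generate a pair of flow waveforms with a known foot-to-foot delay
#'
#' Both waveforms share the same shape family so the true transit time is
#' exactly the difference of the specified foot times.
#'
#' @param spec1,spec2 [waveform_spec]s with identical sampling intervals.
#' @param locations Length-2 character labels.
#' @return `list(w1, w2, true_delay)` with `true_delay` in ms.
#' @export
make_flow_pair <- function(spec1, spec2, locations = c("ASC", "DESC")) {
  if (abs(spec1$sampling - spec2$sampling) > 1e-12)
    stop("waveform specs must share the same sampling interval")
  list(w1 = synth_waveform(spec1, locations[1]),
       w2 = synth_waveform(spec2, locations[2]),
       true_delay = spec2$foot_time - spec1$foot_time)
}

#' Generate a synthetic phase-contrast frame stack
#'
#' Each phase holds a disk of parabolic through-plane velocity (peak at the
#' centre, zero at the lumen edge), plus a magnitude image of the disk. The
#' analytic volumetric flow of phase k is `peak_velocity[k] * pi * r^2 / 2`.
#'
#' @param lumen_radius Disk radius in mm.
#' @param centre Disk centre in mm (2-vector, pixel-centre frame).
#' @param peak_velocity Vector of per-phase peak velocities (mm/s).
#' @param frame_dim Frame size in pixels (2-vector).
#' @param pixel_size Pixel size in mm.
#' @return `list(velocity = nx x ny x nphases array (mm/s), magnitude =
#'   same-shaped array, pixel_size, centre, radius, analytic_flow_ml_s)`.
#' @export
make_pc_stack <- function(lumen_radius = 15, centre = c(32, 32),
                          peak_velocity = rep(1000, 8),
                          frame_dim = c(64, 64), pixel_size = 1) {
  stopifnot(lumen_radius > 0, pixel_size > 0)
  if (any(centre - lumen_radius < 0) ||
      any(centre + lumen_radius > (frame_dim - 1) * pixel_size))
    stop("disk does not fit inside the frame")
  xs <- (seq_len(frame_dim[1]) - 1) * pixel_size
  ys <- (seq_len(frame_dim[2]) - 1) * pixel_size
  r2 <- outer((xs - centre[1])^2, (ys - centre[2])^2, `+`)
  prof <- pmax(1 - r2 / lumen_radius^2, 0)
  np <- length(peak_velocity)
  vel <- array(0, dim = c(frame_dim, np))
  mag <- array(0, dim = c(frame_dim, np))
  disk <- r2 < lumen_radius^2
  for (k in seq_len(np)) {
    vel[, , k] <- peak_velocity[k] * prof
    mag[, , k] <- ifelse(disk, 100, 10)
  }
  list(velocity = vel, magnitude = mag, pixel_size = pixel_size,
       centre = centre, radius = lumen_radius,
       analytic_flow_ml_s = peak_velocity * pi * lumen_radius^2 / 2 / 1000)
}

#' Write / read a ground-truth centreline as CSV
#'
#' CSV columns `x,y,z` in mm, one point per row.
#' @param centreline A [centreline].
#' @param path File path.
#' @return The path (write) or a [centreline] (read).
#' @export
write_centreline_csv <- function(centreline, path) {
  utils::write.csv(data.frame(x = centreline$points[, 1],
                              y = centreline$points[, 2],
                              z = centreline$points[, 3]),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_centreline_csv
#' @param label Label for the centreline read from `path`.
#' @export
read_centreline_csv <- function(path, label = "") {
  df <- utils::read.csv(path)
  centreline(as.matrix(df[, c("x", "y", "z")]), label = label)
}

#' Write / read a flow waveform as CSV
#'
#' CSV columns `time_ms,flow_ml_per_s`.
#' @param waveform A [flow_waveform].
#' @param path File path.
#' @export
write_waveform_csv <- function(waveform, path) {
  utils::write.csv(data.frame(time_ms = waveform$times,
                              flow_ml_per_s = waveform$flow),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_waveform_csv
#' @param location Location label for the waveform read from `path`.
#' @export
read_waveform_csv <- function(path, location = "") {
  df <- utils::read.csv(path)
  flow_waveform(df$time_ms, df$flow_ml_per_s, location = location)
}
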