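# Phase-contrast flow processing: lumen circle fitting, waveform
# extraction, foot-to-foot transit time and pulse wave velocity.

#' Volumetric flow waveform
#'
#' @param times Uniformly spaced sample times in ms (>= 8 samples).
#' @param flow Volumetric flow in ml/s.
#' @param location Label: `"ASC"`, `"DESC"`, `"DIAPH"`, or free text.
#' @return An object of class `flow_waveform`.
#' @export
flow_waveform <- function(times, flow, location = "") {
  times <- as.numeric(times)
  flow <- as.numeric(flow)
  if (length(times) != length(flow) || length(times) < 8)
    stop("a waveform needs >= 8 matched samples")
  if (any(!is.finite(times)) || any(!is.finite(flow)))
    stop("waveform samples must be finite")
  dt <- diff(times)
  if (diff(range(dt)) > 1e-9)
    stop("waveform sampling must be uniform")
  structure(list(times = times, flow = flow, dt = dt[1],
                 location = location),
            class = "flow_waveform")
}

#' @export
print.flow_waveform <- function(x, ...) {
  cat("flow_waveform", if (nzchar(x$location)) paste0("[", x$location, "]"),
      ":", length(x$times), "samples @", signif(x$dt, 4), "ms, peak",
      signif(max(x$flow), 4), "ml/s\n")
  invisible(x)
}

# ---- lumen segmentation ----------------------------------------------

# Algebraic least-squares circle fit (Kasa): minimises the algebraic
# residual of x^2 + y^2 = 2 a x + 2 b y + c.
.fit_circle_ls <- function(xy) {
  A <- cbind(2 * xy[, 1], 2 * xy[, 2], 1)
  b <- xy[, 1]^2 + xy[, 2]^2
  sol <- tryCatch(qr.solve(A, b), error = function(e) NULL)
  if (is.null(sol)) return(NULL)
  r2 <- sol[3] + sol[1]^2 + sol[2]^2
  if (r2 <= 0) return(NULL)
  list(centre = sol[1:2], radius = sqrt(r2))
}

#' Fit a circle to the lumen edge of a 2D frame by ray casting
#'
#' Casts `n_rays` rays from the seed; on each ray the lumen edge is the
#' sample of maximum intensity-gradient magnitude within `search_radius`;
#' a least-squares circle is fitted through the edge points.
#'
#' @param frame 2D image matrix (pixel (1,1) centre at (0,0) mm).
#' @param seed 2D seed point in mm, inside the frame.
#' @param search_radius Maximum edge distance in mm.
#' @param pixel_size Pixel size in mm.
#' @param n_rays Number of rays (default 36).
#' @return An object of class `lumen_circle`: `centre` (mm), `radius` (mm).
#' @export
fit_lumen_circle <- function(frame, seed, search_radius = 25,
                             pixel_size = 1, n_rays = 36) {
  stopifnot(is.matrix(frame), search_radius > 0, pixel_size > 0)
  d <- dim(frame)
  if (any(seed < 0) || any(seed > (d - 1) * pixel_size))
    stop("seed lies outside the frame")
  ds <- 0.25 * pixel_size
  svals <- seq(0, search_radius, by = ds)
  rng <- diff(range(frame))
  edges <- matrix(NA_real_, 0, 2)
  for (k in seq_len(n_rays)) {
    th <- 2 * pi * (k - 1) / n_rays
    dir2 <- c(cos(th), sin(th))
    px <- cbind(seed[1] + svals * dir2[1], seed[2] + svals * dir2[2]) /
      pixel_size
    iv <- .bilinear(frame, px)
    if (rng == 0 || diff(range(iv)) < 0.05 * rng) next
    g <- abs(diff(iv)) / ds
    skip <- max(2L, ceiling(1 / ds))
    if (length(g) <= skip) next
    j <- skip + which.max(g[(skip + 1):length(g)])
    edges <- rbind(edges,
                   seed + (svals[j] + ds / 2 + .peak_refine(g, j) * ds) * dir2)
  }
  if (nrow(edges) < 6)
    stop("lumen segmentation failed: fewer than 6 edge points")
  fit <- .fit_circle_ls(edges)
  if (is.null(fit))
    stop("lumen segmentation failed: degenerate circle fit")
  structure(list(centre = fit$centre, radius = fit$radius),
            class = "lumen_circle")
}

#' Propagate a lumen segmentation through all phases
#'
#' Phase `k + 1` is fitted with its seed at phase `k`'s fitted centre.
#'
#' @param frames nx x ny x nphases array of frames (magnitude images).
#' @param initial A `lumen_circle` (or a 2D seed point in mm) for phase 1.
#' @param ... Passed to [fit_lumen_circle()].
#' @return List of per-phase `lumen_circle`s.
#' @export
propagate_segmentation <- function(frames, initial, ...) {
  stopifnot(length(dim(frames)) == 3)
  np <- dim(frames)[3]
  seed <- if (inherits(initial, "lumen_circle")) initial$centre
          else as.numeric(initial)
  out <- vector("list", np)
  for (k in seq_len(np)) {
    out[[k]] <- tryCatch(
      fit_lumen_circle(frames[, , k], seed, ...),
      error = function(e) stop("segmentation failed at phase ", k, ": ",
                               conditionMessage(e)))
    seed <- out[[k]]$centre
  }
  out
}

#' Extract a volumetric flow waveform from velocity frames
#'
#' `flow(t) = sum over pixels inside the circle of velocity * pixel_area`,
#' with velocity in mm/s and areas in mm^2, converted to ml/s.
#'
#' @param velocity nx x ny x nphases array of through-plane velocity (mm/s).
#' @param circles List of per-phase `lumen_circle`s (length = nphases).
#' @param pixel_size Pixel size in mm.
#' @param times Per-phase sample times in ms.
#' @param location Waveform label.
#' @return A [flow_waveform] in ml/s.
#' @export
extract_waveform <- function(velocity, circles, pixel_size, times,
                             location = "") {
  stopifnot(length(dim(velocity)) == 3)
  np <- dim(velocity)[3]
  if (length(circles) != np)
    stop("need one lumen circle per phase (", np, " phases, ",
         length(circles), " circles)")
  d <- dim(velocity)[1:2]
  xs <- (seq_len(d[1]) - 1) * pixel_size
  ys <- (seq_len(d[2]) - 1) * pixel_size
  flow <- numeric(np)
  for (k in seq_len(np)) {
    cc <- circles[[k]]
    mask <- outer((xs - cc$centre[1])^2, (ys - cc$centre[2])^2, `+`) <
      cc$radius^2
    flow[k] <- sum(velocity[, , k][mask]) * pixel_size^2 / 1000  # mm^3/s->ml/s
  }
  flow_waveform(times, flow, location = location)
}

# ---- foot-to-foot ----------------------------------------------------

#' Locate the foot of a flow waveform
#'
#' The systolic upstroke is the rising limb up to the global maximum; the
#' upstroke tangent is the least-squares line through the samples whose
#' gradient is at least `gradient_threshold` times the peak upstroke
#' gradient (the "average maximum gradient" window); the baseline is the
#' minimum of the waveform before the upstroke onset. The foot is the
#' continuous-time intersection of tangent and baseline.
#'
#' @param waveform A [flow_waveform].
#' @param gradient_threshold Fraction of the peak upstroke gradient
#'   defining the tangent window (default 0.8).
#' @return An object of class `foot_point`: `foot_time` (ms), `slope`,
#'   `intercept`, `baseline`.
#' @export
waveform_foot <- function(waveform, gradient_threshold = 0.8) {
  stopifnot(inherits(waveform, "flow_waveform"))
  # the foot is a continuous-time quantity: resample the waveform on a fine
  # grid (cubic spline) so the tangent window and intersection are not
  # quantised to the acquisition's temporal resolution
  fine <- min(waveform$dt / 16, 1)
  sp <- stats::spline(waveform$times, waveform$flow,
                      xout = seq(waveform$times[1],
                                 waveform$times[length(waveform$times)],
                                 by = fine), method = "fmm")
  t <- sp$x
  f <- sp$y
  n <- length(f)
  dt <- fine
  g <- c(f[2] - f[1], (f[3:n] - f[1:(n - 2)]) / 2, f[n] - f[n - 1]) / dt
  ipk <- which.max(f)
  if (ipk < 3) stop("no systolic upstroke: waveform peaks at its start")
  rise <- 1:ipk
  gmax <- max(g[rise])
  img <- rise[which.max(g[rise])]
  if (gmax <= 0 || diff(range(f)) < .Machine$double.eps * max(abs(f), 1) ||
      gmax * waveform$dt < 1e-3 * diff(range(f)))
    stop("no detectable systolic upstroke (flat or monotone-decreasing)")
  thr <- gradient_threshold * gmax
  lo <- img
  while (lo > 1 && g[lo - 1] >= thr) lo <- lo - 1
  hi <- img
  while (hi < ipk && g[hi + 1] >= thr) hi <- hi + 1
  win <- lo:hi
  if (length(win) >= 2) {
    fit <- stats::lm.fit(cbind(1, t[win]), f[win])
    intercept <- fit$coefficients[1]
    slope <- fit$coefficients[2]
  } else {
    slope <- g[img]
    intercept <- f[img] - slope * t[img]
  }
  if (!is.finite(slope) || slope <= 0)
    stop("no detectable systolic upstroke (non-positive tangent slope)")
  # upstroke onset: last sample before the peak-gradient sample whose
  # gradient falls below 10% of the maximum; baseline = preceding minimum
  onset <- img
  while (onset > 1 && g[onset - 1] > 0.1 * gmax) onset <- onset - 1
  baseline <- min(f[1:onset])
  foot <- (baseline - intercept) / slope
  if (foot < t[1] - waveform$dt || foot > t[n])
    stop("estimated foot lies outside the waveform support")
  structure(list(foot_time = unname(foot), slope = unname(slope),
                 intercept = unname(intercept), baseline = baseline),
            class = "foot_point")
}

#' Foot-to-foot transit time between two waveforms
#'
#' `transit = foot(w2) - foot(w1)` in ms (signed; a negative value means
#' the second waveform's foot precedes the first).
#'
#' @param w1,w2 [flow_waveform]s.
#' @param gradient_threshold Passed to [waveform_foot()].
#' @return Transit time in ms with the two `foot_point`s attached as
#'   attribute `"feet"`.
#' @export
foot_to_foot <- function(w1, w2, gradient_threshold = 0.8) {
  f1 <- waveform_foot(w1, gradient_threshold)
  f2 <- waveform_foot(w2, gradient_threshold)
  structure(f2$foot_time - f1$foot_time, feet = list(f1, f2))
}

#' Pulse wave velocity of an aortic segment
#'
#' `PWV = length / transit_time`; mm/ms is numerically identical to m/s.
#'
#' @param length Centreline length between the two planes in mm (> 0).
#' @param transit_time Foot-to-foot transit time in ms (> 0).
#' @param segment Label: `"ASC-DESC"`, `"DESC-DIAPH"` or `"ASC-DIAPH"`.
#' @return An object of class `pwv_result`: `segment`, `length_mm`,
#'   `transit_ms`, `pwv_m_per_s`.
#' @export
compute_pwv <- function(length, transit_time, segment = "") {
  if (!is.finite(transit_time) || transit_time <= 0)
    stop("non-physical transit time (must be > 0 ms)")
  if (!is.finite(length) || length <= 0)
    stop("segment length must be > 0 mm")
  structure(list(segment = segment, length_mm = length,
                 transit_ms = transit_time,
                 pwv_m_per_s = length / transit_time),
            class = "pwv_result")
}

#' @export
print.pwv_result <- function(x, ...) {
  cat(sprintf("PWV %-10s length %8.2f mm, transit %7.2f ms  ->  %5.2f m/s\n",
              x$segment, x$length_mm, x$transit_ms, x$pwv_m_per_s))
  invisible(x)
}
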