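# Bidirectional fast marching on a vesselness-derived speed map.

#' Build a speed map from a vesselness map
#'
#' `speed = response + floor`. The floor keeps the eikonal equation solvable
#' everywhere while making off-vessel travel slow (default 1e-3, i.e. about
#' a thousand-fold slower than travel along a fully vessel-like voxel).
#'
#' @param vesselness A [vesselness_map].
#' @param floor Strictly positive dimensionless floor.
#' @return An object of class `speed_map`.
#' @export
build_speed_map <- function(vesselness, floor = 1e-3) {
  stopifnot(inherits(vesselness, "vesselness_map"), floor > 0)
  structure(list(speed = vesselness$response + floor,
                 spacing = vesselness$spacing, origin = vesselness$origin,
                 direction = vesselness$direction, floor = floor),
            class = "speed_map")
}

#' Uniform speed map on a given geometry (mainly for testing)
#' @param dim Grid size (3-vector).
#' @param value Speed value (> 0).
#' @param spacing,origin,direction Grid geometry.
#' @return A `speed_map`.
#' @export
uniform_speed_map <- function(dim, value = 1, spacing = c(1, 1, 1),
                              origin = c(0, 0, 0), direction = diag(3)) {
  stopifnot(value > 0)
  structure(list(speed = array(value, dim = dim), spacing = spacing,
                 origin = origin, direction = direction, floor = value),
            class = "speed_map")
}

.nearest_voxel <- function(geom, world) {
  v <- sweep(matrix(world, nrow = 1), 2, geom$origin, `-`) %*% geom$direction
  v <- drop(v) / geom$spacing
  d <- dim(geom$speed)
  if (any(v < -0.5) || any(v > d - 0.5)) stop("seed lies outside the grid")
  as.integer(pmin(pmax(round(v), 0), d - 1))
}

.vox_world <- function(geom, idx) {
  drop(geom$origin + geom$direction %*% (idx * geom$spacing))
}

#' Fast-marching arrival map from a seed
#'
#' Solves the eikonal equation `|grad T| * F = 1` with an upwind scheme on
#' the 6-neighbourhood, using physical spacings in mm, from the voxel
#' nearest the seed (where `T = 0`). By default one-sided second-order
#' differences are used wherever two accepted in-line upwind neighbours
#' exist (with first-order fallback), which keeps backtraced geodesics
#' accurate to a fraction of a voxel.
#'
#' @param speed A `speed_map`.
#' @param seed World point (mm) inside the grid.
#' @param source_ball Radius (in units of the smallest spacing) of the
#'   exactly initialised ball around the seed; upwind schemes have O(1)
#'   relative error right next to a point source, which this source
#'   factorisation removes. Set to 0 for a bare single-voxel seed.
#' @param order Upwind difference order: 2 (default) or 1.
#' @return An object of class `arrival_map`: `time` array (units mm /
#'   speed-unit) and the seed.
#' @export
fast_march <- function(speed, seed, source_ball = 6, order = 2) {
  stopifnot(inherits(speed, "speed_map"))
  sv <- .nearest_voxel(speed, seed)
  tarr <- fm_arrival_cpp(as.vector(speed$speed), dim(speed$speed),
                         speed$spacing, sv, source_ball, as.integer(order))
  structure(list(time = array(tarr, dim(speed$speed)), seed = seed,
                 seed_voxel = sv, source_ball = source_ball,
                 spacing = speed$spacing,
                 origin = speed$origin, direction = speed$direction),
            class = "arrival_map")
}

#' Upwind consistency residual of an arrival map
#'
#' For each voxel, the relative residual of the discrete upwind scheme:
#' `F^2 * sum_axes max((T - min(T_neighbours))/h, 0)^2 - 1`. It is ~0 at
#' every voxel solved by fast marching (outside the analytically
#' initialised source ball).
#'
#' @param arrival An `arrival_map`.
#' @param speed The `speed_map` it was computed from.
#' @return Array of residuals (NA at the seed voxel and at non-finite
#'   times).
#' @export
eikonal_residual <- function(arrival, speed) {
  T <- arrival$time
  d <- dim(T)
  h <- arrival$spacing
  shift <- function(a, ax, by) {
    idx <- lapply(d, seq_len)
    src <- pmin(pmax(idx[[ax]] + by, 1L), d[ax])
    idx[[ax]] <- src
    do.call(`[`, c(list(a), idx))
  }
  big <- max(T[is.finite(T)]) * 2 + 1
  Tf <- ifelse(is.finite(T), T, big)
  res <- array(0, dim = d)
  for (ax in 1:3) {
    mn <- pmin(shift(Tf, ax, -1L), shift(Tf, ax, 1L))
    res <- res + pmax((Tf - mn) / h[ax], 0)^2
  }
  res <- res * speed$speed^2 - 1
  res[!is.finite(T)] <- NA
  # the seed region is initialised analytically, not by the scheme
  sv <- arrival$seed_voxel
  rmm <- (arrival$source_ball %||% 0) * min(h) + max(h)
  ii <- which((slice.index(T, 1) - 1 - sv[1])^2 * h[1]^2 +
                (slice.index(T, 2) - 1 - sv[2])^2 * h[2]^2 +
                (slice.index(T, 3) - 1 - sv[3])^2 * h[3]^2 <= rmm^2)
  res[ii] <- NA
  res
}

# Gradient-descent backtrace on a trilinearly interpolated arrival map,
# from a starting world point down to the seed. Step = 0.25 * min spacing;
# falls back to a discrete move to the best 26-neighbour when interpolated
# descent stalls. When `tsum` (the combined T_start + T_end field, finite
# on the doubly-accepted lens) is supplied, each step is followed by a
# transverse correction toward the valley line of tsum: the minimal path is
# exactly the transverse minimum of T_start + T_end, so this removes the
# kink the discrete meeting-voxel choice would otherwise imprint.
.backtrace <- function(tmap, geom, from_world, seed_world, tsum = NULL) {
  big <- max(tmap[is.finite(tmap)]) * 2 + 1
  Tf <- ifelse(is.finite(tmap), tmap, big)
  d <- dim(Tf)
  sp <- geom$spacing
  step <- 0.25 * min(sp)
  hs <- 0.5 * sp
  interp <- function(w) .interp_world(Tf, geom, w)
  alphas <- seq(-0.75, 0.75, by = 0.25) * min(sp)
  correct <- function(pos, dirm) {
    # valley correction: 1D parabola minimisation of tsum along the two
    # axes transverse to the motion, where tsum is known
    ref <- if (abs(dirm[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u <- .unit(ref - sum(ref * dirm) * dirm)
    v <- .cross3(dirm, u)
    for (axis in list(u, v)) {
      smp <- pos + outer(alphas, axis)
      tv <- .interp_world(tsum, geom, smp)
      if (any(!is.finite(tv))) next
      j <- which.min(tv)
      if (j > 1 && j < length(alphas)) {
        den <- tv[j - 1] - 2 * tv[j] + tv[j + 1]
        frac <- if (den > 0) 0.5 * (tv[j - 1] - tv[j + 1]) / den else 0
        frac <- min(max(frac, -1), 1)
        a_star <- alphas[j] + frac * 0.25 * min(sp)
      } else a_star <- alphas[j] / 3  # damp edge moves
      pos <- pos + 0.5 * a_star * axis  # relaxed update
    }
    pos
  }
  pos <- from_world
  pts <- list(pos)
  cur <- interp(rbind(pos))
  maxit <- 4 * ceiling(sum(d * sp) / step)
  for (it in seq_len(maxit)) {
    if (sqrt(sum((pos - seed_world)^2)) <= max(sp)) break
    probe <- rbind(pos + c(hs[1], 0, 0), pos - c(hs[1], 0, 0),
                   pos + c(0, hs[2], 0), pos - c(0, hs[2], 0),
                   pos + c(0, 0, hs[3]), pos - c(0, 0, hs[3]))
    tv <- interp(probe)
    g <- c((tv[1] - tv[2]) / sp[1], (tv[3] - tv[4]) / sp[2],
           (tv[5] - tv[6]) / sp[3])
    gn <- sqrt(sum(g^2))
    moved <- FALSE
    if (gn > 0) {
      dirm <- -g / gn
      cand <- pos + step * dirm
      if (!is.null(tsum)) cand <- correct(cand, dirm)
      tc <- interp(rbind(cand))
      if (is.finite(tc) && tc < cur) {
        pos <- cand
        cur <- tc
        moved <- TRUE
      }
    }
    if (!moved) {
      # discrete fallback: jump to the lowest-time neighbour voxel centre
      vox <- round(drop(sweep(matrix(pos, 1), 2, geom$origin, `-`) %*%
                          geom$direction) / sp)
      vox <- pmin(pmax(vox, 0), d - 1)
      nb <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
      nb <- nb[rowSums(abs(nb)) > 0, ]
      cand <- sweep(nb, 2, vox, `+`)
      ok <- cand[, 1] >= 0 & cand[, 1] < d[1] & cand[, 2] >= 0 &
        cand[, 2] < d[2] & cand[, 3] >= 0 & cand[, 3] < d[3]
      cand <- cand[ok, , drop = FALSE]
      tv <- Tf[cand + 1L]
      j <- which.min(tv)
      newpos <- drop(geom$origin + geom$direction %*%
                       (cand[j, ] * sp))
      tn <- interp(rbind(newpos))
      if (tn >= cur && sqrt(sum((newpos - seed_world)^2)) > max(sp))
        break  # stalled at a local plateau next to the seed
      pos <- newpos
      cur <- tn
    }
    pts[[length(pts) + 1L]] <- pos
  }
  do.call(rbind, pts)
}

#' Bidirectional fast-marching minimal path between two seeds
#'
#' Wavefronts propagate from both seeds; propagation stops when a voxel has
#' been accepted by both fronts, the meeting voxel is refined as the argmin
#' of `T_start + T_end` over the doubly-accepted set, and the path is the
#' concatenation of steepest-descent backtraces from the meeting voxel to
#' each seed, oriented start to end.
#'
#' @param speed A `speed_map`.
#' @param start,end Distinct world points (mm) inside the grid.
#' @param source_ball Exact-initialisation radius around each seed, as in
#'   [fast_march()].
#' @return An object of class `raw_path`: ordered world points (n x 3).
#' @export
bidirectional_track <- function(speed, start, end, source_ball = 6,
                                order = 2) {
  stopifnot(inherits(speed, "speed_map"))
  sv1 <- .nearest_voxel(speed, start)
  sv2 <- .nearest_voxel(speed, end)
  if (all(sv1 == sv2)) stop("start and end seeds are identical (degenerate)")
  res <- fm_bidirectional_cpp(as.vector(speed$speed), dim(speed$speed),
                              speed$spacing, sv1, sv2, source_ball,
                              as.integer(order))
  if (res$meet_index < 1)
    stop("tracking failure: the fronts never met")
  d <- dim(speed$speed)
  t1 <- array(ifelse(res$accepted_start, res$time_start, Inf), d)
  t2 <- array(ifelse(res$accepted_end, res$time_end, Inf), d)
  mi <- as.integer(res$meet_index) - 1L
  mvox <- c(mi %% d[1], (mi %/% d[1]) %% d[2], mi %/% (d[1] * d[2]))
  geom <- list(origin = speed$origin, direction = speed$direction,
               spacing = speed$spacing, speed = speed$speed)
  mworld <- .vox_world(geom, mvox)
  w1 <- .vox_world(geom, sv1)
  w2 <- .vox_world(geom, sv2)
  tsum <- t1 + t2
  half1 <- .backtrace(t1, geom, mworld, w1, tsum)  # meet -> start
  half2 <- .backtrace(t2, geom, mworld, w2, tsum)  # meet -> end
  pts <- rbind(w1, half1[rev(seq_len(nrow(half1))), , drop = FALSE],
               half2, w2)
  keep <- c(TRUE, rowSums((pts[-1, , drop = FALSE] -
                             pts[-nrow(pts), , drop = FALSE])^2) > 1e-16)
  structure(list(points = pts[keep, , drop = FALSE],
                 meet_point = mworld, start = start, end = end),
            class = "raw_path")
}

#' @export
print.raw_path <- function(x, ...) {
  cat("raw_path:", nrow(x$points), "points,",
      signif(sum(sqrt(rowSums(diff(x$points)^2))), 5), "mm\n")
  invisible(x)
}

#' Detect a tracking failure (path leaving the lumen)
#'
#' A tracing is failed when any path point lies outside the lumen. The lumen
#' may be given analytically (ground-truth centreline points plus the lumen
#' radius) or as a binary mask volume.
#'
#' @param path A `raw_path` or [centreline].
#' @param lumen Either a [centreline]/matrix of ground-truth points (used
#'   with `lumen_radius`), or a [volume_image] binary mask (> 0 inside).
#' @param lumen_radius Lumen radius in mm (analytic form only).
#' @return `list(failed, first_exit_arc_mm, n_outside)`; `first_exit_arc_mm`
#'   is the arc-length position along the path of the first point outside.
#' @export
detect_failure <- function(path, lumen, lumen_radius = NULL) {
  pts <- if (inherits(path, "raw_path")) path$points
         else if (inherits(path, "centreline")) path$points
         else as.matrix(path)
  if (inherits(lumen, "volume_image")) {
    inside <- .interp_world(lumen$data, lumen, pts) > 0.5
  } else {
    ref <- if (inherits(lumen, "centreline")) lumen$points else as.matrix(lumen)
    if (nrow(ref) == 0) {
      inside <- rep(FALSE, nrow(pts))
    } else {
      if (is.null(lumen_radius))
        stop("lumen_radius is required with an analytic lumen")
      inside <- .min_dist_to_set(pts, ref) < lumen_radius
    }
  }
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                         pts[-nrow(pts), , drop = FALSE])^2))
  arc <- c(0, cumsum(seg))
  out <- which(!inside)
  list(failed = length(out) > 0,
       first_exit_arc_mm = if (length(out)) arc[out[1]] else NA_real_,
       n_outside = length(out))
}
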