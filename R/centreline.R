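#' Centreline container
#'
#' An ordered polyline of 3D world points (mm) through the centroid of a
#' vessel. Exactly coincident consecutive points are collapsed.
#'
#' @param points n x 3 matrix of world points (mm), n >= 2, all finite.
#' @param label Free-text label (e.g. `"ASC-DIAPH"`).
#' @return An object of class `centreline`.
#' @export
centreline <- function(points, label = "") {
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("points must have three columns")
  if (any(!is.finite(points))) stop("centreline points must be finite")
  if (nrow(points) >= 2) {
    dup <- c(FALSE, rowSums((points[-1, , drop = FALSE] -
                               points[-nrow(points), , drop = FALSE])^2) == 0)
    points <- points[!dup, , drop = FALSE]
  }
  if (nrow(points) < 2) stop("a centreline needs at least 2 distinct points")
  structure(list(points = points, label = label), class = "centreline")
}

#' @export
print.centreline <- function(x, ...) {
  cat("centreline", if (nzchar(x$label)) paste0("[", x$label, "]"), ":",
      nrow(x$points), "points,", signif(arc_length(x), 6), "mm\n")
  invisible(x)
}

#' Arc length of a centreline (mm)
#'
#' Sum of consecutive Euclidean distances.
#' @param centreline A [centreline] (or n x 3 point matrix).
#' @return Length in mm.
#' @export
arc_length <- function(centreline) {
  p <- if (inherits(centreline, "centreline")) centreline$points
       else as.matrix(centreline)
  sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}

.cumulative_arc <- function(p) {
  c(0, cumsum(sqrt(rowSums((p[-1, , drop = FALSE] -
                              p[-nrow(p), , drop = FALSE])^2))))
}

#' Resample a centreline at uniform arc-length spacing
#'
#' Arc-length parameterised linear interpolation. Output points sit at
#' `0, spacing, 2*spacing, ...`; the final interval may be shorter so the
#' end point is preserved exactly.
#'
#' @param centreline A [centreline].
#' @param spacing Target spacing in mm (default 0.1).
#' @return A resampled [centreline].
#' @export
resample_centreline <- function(centreline, spacing = 0.1) {
  stopifnot(inherits(centreline, "centreline"), spacing > 0)
  p <- centreline$points
  s <- .cumulative_arc(p)
  L <- s[length(s)]
  if (L <= 0) stop("degenerate centreline: zero length")
  so <- seq(0, L, by = spacing)
  if (L - so[length(so)] > 1e-9 * max(1, L)) so <- c(so, L)
  out <- cbind(stats::approx(s, p[, 1], xout = so)$y,
               stats::approx(s, p[, 2], xout = so)$y,
               stats::approx(s, p[, 3], xout = so)$y)
  out[1, ] <- p[1, ]
  out[nrow(out), ] <- p[nrow(p), ]
  centreline(out, label = centreline$label)
}

#' Split a centreline at the point nearest a landmark
#'
#' Splits at the centreline point minimising the distance to `desc_point`
#' (ties broken toward the smaller arc-length index). Both segments share
#' the split point, so their lengths sum exactly to the parent length.
#'
#' @param centreline A resampled [centreline].
#' @param desc_point World point (mm) marking the descending-aorta level.
#' @return `list(arch, descending)` of [centreline]s (class `segment_pair`).
#' @export
split_at_location <- function(centreline, desc_point) {
  stopifnot(inherits(centreline, "centreline"), all(is.finite(desc_point)))
  p <- centreline$points
  d2 <- rowSums(sweep(p, 2, desc_point, `-`)^2)
  i <- which.min(d2)  # which.min takes the first (smallest index) on ties
  if (i == 1L || i == nrow(p))
    stop("split point coincides with a centreline endpoint")
  structure(list(
    arch = centreline(p[1:i, , drop = FALSE], label = "ASC-DESC"),
    descending = centreline(p[i:nrow(p), , drop = FALSE],
                            label = "DESC-DIAPH")),
    class = "segment_pair")
}

#' Point-wise minimum distance between two centrelines
#'
#' For each point of `test`, the minimum Euclidean distance to any point of
#' `reference` (directional; swap the arguments for the other direction).
#' Both centrelines should be resampled to a fine common spacing first.
#'
#' @param test,reference [centreline]s.
#' @return `list(distances, summary)` where `summary` holds mean, median,
#'   IQR bounds and max (mm).
#' @export
centreline_distance <- function(test, reference) {
  stopifnot(inherits(test, "centreline"), inherits(reference, "centreline"))
  d <- .min_dist_to_set(test$points, reference$points)
  q <- stats::quantile(d, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(distances = d,
       summary = list(mean = mean(d), median = q[2], iqr_lower = q[1],
                      iqr_upper = q[3], max = max(d)))
}

# ---- seed re-centering ------------------------------------------------

# Direct least-squares ellipse fit (stable Halir-Flusser partitioning).
# Returns the conic coefficients (a, b, c, d, e, f) of
# a x^2 + b x y + c y^2 + d x + e y + f = 0, or NULL when degenerate.
.fit_ellipse_conic <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  T3 <- tryCatch(-solve(S3, t(S2)), error = function(e) NULL)
  if (is.null(T3)) return(NULL)
  M <- S1 + S2 %*% T3
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  evec <- Re(ev$vectors)
  cond <- 4 * evec[1, ] * evec[3, ] - evec[2, ]^2
  j <- which(cond > 0)
  if (length(j) == 0) return(NULL)
  a1 <- evec[, j[1]]
  c(a1, drop(T3 %*% a1))
}

.ellipse_centre <- function(conic) {
  a <- conic[1]; b <- conic[2]; cc <- conic[3]; d <- conic[4]; e <- conic[5]
  den <- b^2 - 4 * a * cc
  if (abs(den) < .Machine$double.eps) return(NULL)
  c((2 * cc * d - b * e) / den, (2 * a * e - b * d) / den)
}

#' Re-centre a seed point on the vessel axis by ray-cast ellipse fitting
#'
#' Casts `n_rays` rays in the cross-sectional plane through the seed
#' (normal = `axis_hint`), detects the lumen edge on each ray as the
#' location of maximum intensity-gradient magnitude, fits an ellipse to the
#' edge points by direct least squares, and returns the ellipse centre.
#' Used to correct inter-scan patient motion between the phase-contrast
#' planes (where seeds are defined) and the anatomical volume.
#'
#' @param volume A [volume_image].
#' @param seed World seed point (mm), inside the grid.
#' @param axis_hint Approximate local vessel direction (unit vector).
#' @param search_radius Maximum edge distance from the seed in mm; should
#'   exceed the expected lumen radius.
#' @param n_rays Number of rays (default 36).
#' @return Re-centred world point (within `search_radius` of the input).
#' @export
recenter_seed <- function(volume, seed, axis_hint, search_radius = 15,
                          n_rays = 36) {
  stopifnot(inherits(volume, "volume_image"), search_radius > 0)
  if (!in_grid(volume, seed)) stop("seed lies outside the grid")
  n <- .unit(axis_hint)
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- .unit(ref - sum(ref * n) * n)
  v <- .cross3(n, u)
  ds <- 0.25 * min(volume$spacing)
  svals <- seq(0, search_radius, by = ds)
  rng <- diff(range(volume$data))
  edges <- matrix(NA_real_, 0, 2)
  for (k in seq_len(n_rays)) {
    th <- 2 * pi * (k - 1) / n_rays
    dir2 <- c(cos(th), sin(th))
    dirw <- dir2[1] * u + dir2[2] * v
    pts <- sweep(outer(svals, dirw), 2, seed, `+`)
    iv <- .interp_world(volume$data, volume, pts)
    if (diff(range(iv)) < 0.05 * rng || rng == 0) next  # featureless ray
    g <- abs(diff(iv)) / ds
    skip <- max(2L, ceiling(1 / ds))  # ignore the immediate seed vicinity
    if (length(g) <= skip) next
    j <- skip + which.max(g[(skip + 1):length(g)])
    edges <- rbind(edges, (svals[j] + ds / 2 + .peak_refine(g, j) * ds) * dir2)
  }
  if (nrow(edges) < 6)
    stop("re-centering failed: fewer than 6 valid lumen-edge points")
  conic <- .fit_ellipse_conic(edges)
  ctr <- if (is.null(conic)) NULL else .ellipse_centre(conic)
  if (is.null(ctr) || sqrt(sum(ctr^2)) > search_radius)
    stop("re-centering failed: ellipse fit degenerate or outside the ",
         "search radius")
  drop(seed + ctr[1] * u + ctr[2] * v)
}

# ---- open active contour ---------------------------------------------

#' Open-active-contour parameters
#'
#' @param internal_weight,external_weight Non-negative force weights
#'   (default both 1: equally weighted curvature-minimising and centering
#'   terms).
#' @param step Relaxation factor in (0, 1]: fraction of the semi-implicit
#'   update applied per iteration (1 = full update).
#' @param max_iter Iteration cap.
#' @param tol Convergence tolerance: maximum point displacement (mm) below
#'   which evolution stops.
#' @param control_spacing Control-point spacing (mm) the input chain is
#'   decimated to before evolution.
#' @param centring_rays Rays per point for the lumen-centring force.
#' @param centring_radius Maximum lumen-edge search distance in mm.
#' @return An object of class `snake_params`.
#' @export
snake_params <- function(internal_weight = 1, external_weight = 1,
                         step = 1, max_iter = 50, tol = 0.01,
                         control_spacing = 1, centring_rays = 16,
                         centring_radius = 15) {
  stopifnot(internal_weight >= 0, external_weight >= 0, step > 0, step <= 1,
            max_iter >= 1, tol > 0, control_spacing > 0, centring_rays >= 6,
            centring_radius > 0)
  structure(list(internal_weight = internal_weight,
                 external_weight = external_weight, step = step,
                 max_iter = max_iter, tol = tol,
                 control_spacing = control_spacing,
                 centring_rays = centring_rays,
                 centring_radius = centring_radius),
            class = "snake_params")
}

# Per-point lumen centres in the plane normal to the local tangent:
# cast rays from each point, take the max-|gradient| sample as the lumen
# edge, and fit a least-squares circle through the edges. Returns an
# n x 3 matrix of world targets with NA rows where no reliable centre was
# found (< 6 valid edges or degenerate fit).
.lumen_centres <- function(p, volume, n_rays, radius) {
  n <- nrow(p)
  tang <- rbind(p[2, ] - p[1, ],
                p[3:n, , drop = FALSE] - p[1:(n - 2), , drop = FALSE],
                p[n, ] - p[n - 1, ])
  tn <- sqrt(rowSums(tang^2)); tn[tn == 0] <- 1
  tang <- tang / tn
  pick <- abs(tang[, 1]) < 0.9
  ref <- cbind(ifelse(pick, 1, 0), ifelse(pick, 0, 1), 0)
  u <- ref - tang * rowSums(ref * tang)
  u <- u / sqrt(rowSums(u^2))
  v <- cbind(tang[, 2] * u[, 3] - tang[, 3] * u[, 2],
             tang[, 3] * u[, 1] - tang[, 1] * u[, 3],
             tang[, 1] * u[, 2] - tang[, 2] * u[, 1])
  ds <- 0.25 * min(volume$spacing)
  svals <- seq(0, radius, by = ds)
  ns <- length(svals)
  th <- 2 * pi * (seq_len(n_rays) - 1) / n_rays
  centres <- matrix(NA_real_, n, 3)
  rng <- diff(range(volume$data))
  skip <- max(2L, ceiling(1 / ds))
  for (i in seq_len(n)) {
    dirs <- outer(cos(th), u[i, ]) + outer(sin(th), v[i, ])  # n_rays x 3
    pts <- matrix(rep(p[i, ], each = ns * n_rays), ncol = 3) +
      dirs[rep(seq_len(n_rays), each = ns), ] * svals
    iv <- matrix(.interp_world(volume$data, volume, pts), nrow = ns)
    g <- abs(diff(iv)) / ds
    ok <- apply(iv, 2, function(col) diff(range(col))) >= 0.05 * rng &
      rng > 0
    if (sum(ok) < 6) next
    j <- skip + apply(g[(skip + 1):nrow(g), , drop = FALSE], 2, which.max)
    dj <- vapply(seq_along(j), function(q) .peak_refine(g[, q], j[q]),
                 numeric(1))
    edge_s <- svals[j] + ds / 2 + dj * ds
    e2 <- cbind(edge_s * cos(th), edge_s * sin(th))[ok, , drop = FALSE]
    fit <- .fit_circle_ls(e2)
    if (is.null(fit) || sqrt(sum(fit$centre^2)) > radius) next
    centres[i, ] <- p[i, ] + fit$centre[1] * u[i, ] + fit$centre[2] * v[i, ]
  }
  centres
}

#' Refine a raw path with an open active contour
#'
#' Evolves the point chain under two equally weighted terms with fixed
#' endpoints: an internal second-difference (curvature-minimising)
#' regulariser, and an external centring term that pulls each point toward
#' the centre of the lumen in the plane normal to the local tangent. The
#' lumen centre is found per point by ray casting in the normal plane (edge
#' = maximum intensity-gradient location) and a least-squares circle fit.
#' Each iteration solves the regularised least-squares system
#' semi-implicitly, then re-estimates the centres; evolution stops when the
#' largest point displacement falls below `params$tol`.
#'
#' @param path A `raw_path` or [centreline].
#' @param volume The intensity [volume_image] the path was tracked in.
#' @param params A [snake_params].
#' @param trace If `TRUE`, attach the point chain after every iteration as
#'   attribute `"trace"` (for convergence diagnostics).
#' @param decimate Decimate the chain to `params$control_spacing` before
#'   evolution (default `TRUE`).
#' @return A refined [centreline].
#' @export
refine_active_contour <- function(path, volume, params = snake_params(),
                                  trace = FALSE, decimate = TRUE) {
  stopifnot(inherits(volume, "volume_image"))
  p <- if (inherits(path, "raw_path")) path$points
       else if (inherits(path, "centreline")) path$points
       else as.matrix(path)
  if (decimate && nrow(p) >= 2)
    p <- resample_centreline(centreline(p),
                             spacing = params$control_spacing)$points
  n <- nrow(p)
  if (n < 3) return(centreline(p))
  d <- dim(volume$data)
  # second-difference operator rows (n-2) x n and its normal matrix
  M <- matrix(0, n - 2, n)
  for (i in seq_len(n - 2)) M[i, i:(i + 2)] <- c(1, -2, 1)
  K <- crossprod(M)
  interior <- 2:(n - 1)
  KII <- K[interior, interior, drop = FALSE]
  KIB <- K[interior, c(1, n), drop = FALSE]
  wi <- params$internal_weight
  we <- params$external_weight
  hist <- if (trace) vector("list", params$max_iter) else NULL
  iters <- 0L
  for (it in seq_len(params$max_iter)) {
    iters <- it
    ctr <- .lumen_centres(p, volume, params$centring_rays,
                          params$centring_radius)
    w <- as.numeric(!is.na(ctr[, 1]))[interior]
    ctr[is.na(ctr)] <- 0
    A <- wi * KII + diag(we * w, length(interior))
    if (wi == 0 && all(w == 0)) break
    rhs <- we * w * ctr[interior, , drop = FALSE] -
      wi * KIB %*% p[c(1, n), , drop = FALSE]
    sol <- solve(A, rhs)
    newp <- p
    newp[interior, ] <- (1 - params$step) * p[interior, , drop = FALSE] +
      params$step * sol
    disp <- sqrt(rowSums((newp - p)^2))
    p <- newp
    vox <- sweep(p, 2, volume$origin, `-`) %*% volume$direction
    vox <- sweep(vox, 2, volume$spacing, `/`)
    if (any(vox < -0.5) || any(sweep(vox, 2, d - 0.5, `>`)))
      stop("active contour diverged: a point left the grid at iteration ", it)
    if (trace) hist[[it]] <- p
    mdisp <- max(disp)
    if (mdisp < params$tol) break
    # plateau: the centring targets carry a small estimation noise floor,
    # so displacements stop shrinking once the chain sits on the lumen
    # centres; averaging the last two chains halves the residual wobble
    if (it >= 3 && mdisp < 0.2 && exists("prev_mdisp") &&
        mdisp > 0.8 * prev_mdisp) {
      p[interior, ] <- (p[interior, , drop = FALSE] +
                          prev_p[interior, , drop = FALSE]) / 2
      if (trace) hist[[it]] <- p
      break
    }
    prev_mdisp <- mdisp
    prev_p <- p
  }
  out <- centreline(p)
  attr(out, "iterations") <- iters
  if (trace) attr(out, "trace") <- hist[seq_len(iters)]
  out
}
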