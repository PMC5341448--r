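# Oblique-sagittal plane handling: the "2D method" arm of the 2D-vs-3D
# length comparison.

#' Fit an oblique-sagittal plane to a 3D centreline
#'
#' Total-least-squares plane through the centreline points (minimising the
#' sum of squared orthogonal distances, via SVD of the centred point cloud).
#' The normal is oriented toward the positive left-right (world x) axis.
#'
#' @param centreline A [centreline] with at least 3 non-collinear points.
#' @return A [plane_def] through the point centroid.
#' @export
fit_oblique_sagittal <- function(centreline) {
  p <- if (inherits(centreline, "centreline")) centreline$points
       else as.matrix(centreline)
  if (nrow(p) < 3) stop("need at least 3 points to fit a plane")
  ctr <- colMeans(p)
  q <- sweep(p, 2, ctr, `-`)
  sv <- svd(q)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1))
    stop("degenerate plane: centreline points are collinear")
  normal <- sv$v[, 3]
  if (normal[1] < 0) normal <- -normal
  u <- sv$v[, 1]
  v <- .cross3(normal, u)
  plane_def(ctr, normal, in_plane_axes = rbind(u, v))
}

#' Project a 3D centreline orthogonally onto a plane
#'
#' Each point is projected orthogonally and expressed in the plane's
#' in-plane coordinates. The 2D arc length can never exceed the 3D arc
#' length, with equality only for curves parallel to the plane — the
#' geometric reason 2D length measurements underestimate tortuous vessels.
#'
#' @param centreline A [centreline].
#' @param plane A [plane_def].
#' @return An object of class `projected_centreline`: `points2d` (n x 2,
#'   mm), `plane`, `source = "projected"`.
#' @export
project_to_plane <- function(centreline, plane) {
  stopifnot(inherits(plane, "plane_def"))
  p <- if (inherits(centreline, "centreline")) centreline$points
       else as.matrix(centreline)
  q <- sweep(p, 2, plane$point, `-`)
  uv <- q %*% t(plane$in_plane_axes)
  structure(list(points2d = uv, plane = plane, source = "projected"),
            class = "projected_centreline")
}

#' Arc length of a projected (2D) centreline
#' @param projected A `projected_centreline` (or n x 2 matrix).
#' @return Length in mm.
#' @export
arc_length_2d <- function(projected) {
  p <- if (inherits(projected, "projected_centreline")) projected$points2d
       else as.matrix(projected)
  sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}

#' Intersection of a flow plane with the 2D measurement plane
#'
#' The 3D line where the two planes meet, expressed in the 2D plane's
#' in-plane coordinates. Used to mark where a 2D centreline must be clipped
#' (the manual-annotation start/end definition).
#'
#' @param plane2d The measurement [plane_def] (carrying the 2D frame).
#' @param flow_plane The phase-contrast acquisition [plane_def].
#' @return `list(point, direction)` in 2D plane coordinates (mm; direction
#'   unit-norm), class `plane_line`.
#' @export
flow_plane_marks <- function(plane2d, flow_plane) {
  n1 <- plane2d$normal
  n2 <- flow_plane$normal
  d3 <- .cross3(n1, n2)
  if (sqrt(sum(d3^2)) < 1e-9)
    stop("planes are parallel: no intersection line")
  A <- rbind(n1, n2, d3)
  b <- c(sum(n1 * plane2d$point), sum(n2 * flow_plane$point),
         sum(d3 * plane2d$point))
  p3 <- solve(A, b)
  to2d <- function(w) drop(plane2d$in_plane_axes %*% w)
  pt2 <- to2d(p3 - plane2d$point)
  dir2 <- to2d(d3)
  dn <- sqrt(sum(dir2^2))
  if (dn < 1e-12) stop("intersection line is perpendicular to the plane")
  structure(list(point = pt2, direction = dir2 / dn), class = "plane_line")
}

# Signed perpendicular distance of 2D points to a plane_line.
.signed_dist_2d <- function(pts, line) {
  dx <- pts[, 1] - line$point[1]
  dy <- pts[, 2] - line$point[2]
  line$direction[1] * dy - line$direction[2] * dx
}

#' Clip a 2D centreline between two flow-plane marks
#'
#' Finds the first crossing of each mark line along the polyline (linear
#' interpolation between samples) and returns the sub-polyline between the
#' two crossings, with interpolated endpoints.
#'
#' @param projected A `projected_centreline`.
#' @param mark_start,mark_end `plane_line`s from [flow_plane_marks()].
#' @return A clipped `projected_centreline`.
#' @export
clip_at_marks <- function(projected, mark_start, mark_end) {
  p <- projected$points2d
  crossing <- function(line) {
    sd <- .signed_dist_2d(p, line)
    z <- which(abs(sd) < 1e-12)
    if (length(z)) return(list(idx = z[1], frac = 0))
    sgn <- sd[-1] * sd[-length(sd)]
    k <- which(sgn < 0)
    if (!length(k)) stop("centreline does not cross a flow-plane mark")
    k <- k[1]
    list(idx = k, frac = sd[k] / (sd[k] - sd[k + 1]))
  }
  ca <- crossing(mark_start)
  cb <- crossing(mark_end)
  at <- function(cr) p[cr$idx, ] + cr$frac * (p[min(cr$idx + 1, nrow(p)), ] -
                                                p[cr$idx, ])
  sa <- ca$idx + ca$frac
  sb <- cb$idx + cb$frac
  if (sa > sb) { tmp <- ca; ca <- cb; cb <- tmp; tmp <- sa; sa <- sb; sb <- tmp }
  mid <- if (ceiling(sa) <= floor(sb))
    p[seq(ceiling(sa), floor(sb)), , drop = FALSE] else NULL
  pts <- rbind(at(ca), mid, at(cb))
  keep <- c(TRUE, rowSums((pts[-1, , drop = FALSE] -
                             pts[-nrow(pts), , drop = FALSE])^2) > 1e-18)
  structure(list(points2d = pts[keep, , drop = FALSE],
                 plane = projected$plane, source = projected$source),
            class = "projected_centreline")
}

#' Apply a rigid transform to a centreline (patient-motion simulation)
#'
#' Rotates the centreline about a centre and translates it, while any flow
#' planes stay fixed — the mechanism by which patient motion between the
#' anatomical and phase-contrast scans changes clipped 2D lengths without
#' changing the true arc length.
#'
#' @param centreline A [centreline].
#' @param rotation 3x3 rotation matrix (orthonormal, det +1).
#' @param translation Length-3 translation in mm.
#' @param centre Rotation centre; defaults to the point centroid.
#' @return The transformed [centreline].
#' @export
simulate_motion <- function(centreline, rotation = diag(3),
                            translation = c(0, 0, 0), centre = NULL) {
  stopifnot(inherits(centreline, "centreline"))
  rotation <- as.matrix(rotation)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9)
    stop("rotation must be a proper orthonormal matrix")
  p <- centreline$points
  if (is.null(centre)) centre <- colMeans(p)
  q <- sweep(p, 2, centre, `-`) %*% t(rotation)
  q <- sweep(q, 2, centre + translation, `+`)
  centreline(q, label = centreline$label)
}
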