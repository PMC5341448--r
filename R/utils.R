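# Internal numeric helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("cannot normalise a zero vector")
  v / n
}

# Trilinear interpolation of a 3D array at fractional 0-based voxel
# coordinates (n x 3 matrix). Coordinates are clamped to the grid so
# evaluation just outside the boundary replicates the edge.
.trilinear <- function(arr, vox) {
  d <- dim(arr)
  x <- pmin(pmax(vox[, 1], 0), d[1] - 1)
  y <- pmin(pmax(vox[, 2], 0), d[2] - 1)
  z <- pmin(pmax(vox[, 3], 0), d[3] - 1)
  x0 <- pmin(floor(x), d[1] - 2); x0 <- pmax(x0, 0)
  y0 <- pmin(floor(y), d[2] - 2); y0 <- pmax(y0, 0)
  z0 <- pmin(floor(z), d[3] - 2); z0 <- pmax(z0, 0)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  ix <- function(i, j, k) arr[cbind(i + 1, j + 1, k + 1)]
  c000 <- ix(x0, y0, z0);     c100 <- ix(x0 + 1, y0, z0)
  c010 <- ix(x0, y0 + 1, z0); c110 <- ix(x0 + 1, y0 + 1, z0)
  c001 <- ix(x0, y0, z0 + 1); c101 <- ix(x0 + 1, y0, z0 + 1)
  c011 <- ix(x0, y0 + 1, z0 + 1); c111 <- ix(x0 + 1, y0 + 1, z0 + 1)
  c00 <- c000 * (1 - fx) + c100 * fx
  c10 <- c010 * (1 - fx) + c110 * fx
  c01 <- c001 * (1 - fx) + c101 * fx
  c11 <- c011 * (1 - fx) + c111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  c0 * (1 - fz) + c1 * fz
}

# Interpolate a scalar grid that shares a volume_image's geometry at world
# points (n x 3, mm).
.interp_world <- function(arr, geom, world) {
  if (!is.matrix(world)) world <- matrix(world, nrow = 1)
  vox <- sweep(world, 2, geom$origin, `-`) %*% geom$direction
  vox <- sweep(vox, 2, geom$spacing, `/`)
  .trilinear(arr, vox)
}

# Bilinear interpolation of a 2D image at fractional 0-based pixel coords.
.bilinear <- function(img, px) {
  d <- dim(img)
  x <- pmin(pmax(px[, 1], 0), d[1] - 1)
  y <- pmin(pmax(px[, 2], 0), d[2] - 1)
  x0 <- pmax(pmin(floor(x), d[1] - 2), 0)
  y0 <- pmax(pmin(floor(y), d[2] - 2), 0)
  fx <- x - x0; fy <- y - y0
  v00 <- img[cbind(x0 + 1, y0 + 1)]
  v10 <- img[cbind(x0 + 2, y0 + 1)]
  v01 <- img[cbind(x0 + 1, y0 + 2)]
  v11 <- img[cbind(x0 + 2, y0 + 2)]
  (v00 * (1 - fx) + v10 * fx) * (1 - fy) + (v01 * (1 - fx) + v11 * fx) * fy
}

# Run code with a temporarily seeded RNG, restoring the caller's stream.
.with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Minimum distance from each row of `pts` to the point set `ref`, chunked to
# bound memory.
.min_dist_to_set <- function(pts, ref, chunk = 512L) {
  n <- nrow(pts)
  out <- numeric(n)
  rx <- ref[, 1]; ry <- ref[, 2]; rz <- ref[, 3]
  for (i0 in seq(1L, n, by = chunk)) {
    i1 <- min(i0 + chunk - 1L, n)
    dx <- outer(pts[i0:i1, 1], rx, `-`)
    dy <- outer(pts[i0:i1, 2], ry, `-`)
    dz <- outer(pts[i0:i1, 3], rz, `-`)
    out[i0:i1] <- sqrt(apply(dx * dx + dy * dy + dz * dz, 1, min))
  }
  out
}

# Sub-sample refinement of a gradient-peak index by parabolic
# interpolation; returns the fractional offset in [-0.5, 0.5] sample units.
.peak_refine <- function(g, j) {
  if (j <= 1 || j >= length(g)) return(0)
  den <- g[j - 1] - 2 * g[j] + g[j + 1]
  if (den >= 0) return(0)
  min(max(0.5 * (g[j - 1] - g[j + 1]) / den, -0.5), 0.5)
}
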