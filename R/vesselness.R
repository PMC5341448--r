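# Multi-scale Hessian tubularity filtering.
#
# Second derivatives are taken in scale space: the volume is convolved with
# sampled Gaussian-derivative kernels, separably per axis, with replicate
# boundary handling. Anisotropic grids are handled by expressing the scale
# (a physical sigma in mm) in per-axis voxel units, and derivative kernels
# carry 1/spacing factors so all derivatives are per-mm.

# 1D sampled Gaussian kernel of derivative order 0, 1 or 2 (voxel units).
.gauss_kernel <- function(sigma, order = 0L) {
  r <- max(3L, ceiling(4 * sigma))
  x <- seq(-r, r)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  k <- switch(as.character(order),
              "0" = g,
              "1" = -x / sigma^2 * g,
              "2" = (x^2 - sigma^2) / sigma^4 * g)
  if (order == 2L) k <- k - mean(k)   # exact zero response on constants
  k
}

# Dense convolution operator (n x n) for a symmetric-support kernel with
# replicate (clamp-to-edge) boundaries.
.conv_operator <- function(n, kernel) {
  r <- (length(kernel) - 1L) / 2L
  K <- matrix(0, n, n)
  for (t in seq_along(kernel)) {
    off <- t - r - 1L
    j <- pmin(pmax(seq_len(n) + off, 1L), n)
    K[cbind(seq_len(n), j)] <- K[cbind(seq_len(n), j)] + kernel[t]
  }
  K
}

# Convolve a 3D array along one axis with a 1D kernel.
.convolve_axis <- function(arr, kernel, axis) {
  d <- dim(arr)
  K <- .conv_operator(d[axis], kernel)
  perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  a <- aperm(arr, perm)
  da <- dim(a)
  a <- K %*% matrix(a, nrow = da[1])
  dim(a) <- da
  aperm(a, order(perm))
}

#' Separable Gaussian blur of a 3D array
#'
#' @param arr 3D numeric array.
#' @param sigma_vox Per-axis Gaussian sigma in voxel units (scalar recycled).
#' @return Blurred array of the same shape.
#' @export
gaussian_blur <- function(arr, sigma_vox) {
  sigma_vox <- rep(as.numeric(sigma_vox), length.out = 3)
  for (ax in 1:3)
    if (sigma_vox[ax] > 0)
      arr <- .convolve_axis(arr, .gauss_kernel(sigma_vox[ax], 0L), ax)
  arr
}

# Scale-space partial derivative: orders (ox, oy, oz) at physical scale
# (mm), gamma-normalised by scale^(sum of orders).
.scale_derivative <- function(arr, orders, scale, spacing) {
  for (ax in 1:3) {
    k <- .gauss_kernel(scale / spacing[ax], orders[ax])
    arr <- .convolve_axis(arr, k, ax)
    if (orders[ax] > 0) arr <- arr / spacing[ax]^orders[ax]
  }
  arr * scale^sum(orders)
}

#' Scale-space Hessian eigenvalues of a volume
#'
#' Computes the six unique second derivatives of the volume at a Gaussian
#' scale (sigma, in mm), gamma-normalised by `scale^2` so responses are
#' comparable across scales, then the per-voxel eigenvalues of the symmetric
#' Hessian sorted by increasing magnitude (`|lambda1| <= |lambda2| <=
#' |lambda3|`).
#'
#' @param volume A [volume_image].
#' @param scale Gaussian sigma in mm; should be at least the largest voxel
#'   spacing (a warning is raised otherwise).
#' @return `list(l1, l2, l3)` of arrays on the volume grid.
#' @export
hessian_eigenvalues <- function(volume, scale) {
  stopifnot(inherits(volume, "volume_image"), scale > 0)
  if (!all(is.finite(volume$data))) stop("volume contains non-finite values")
  if (scale < max(volume$spacing))
    warning("scale ", scale, " mm is below the largest voxel spacing (",
            max(volume$spacing), " mm); derivatives will be under-resolved")
  sp <- volume$spacing
  arr <- volume$data
  h <- list(
    xx = .scale_derivative(arr, c(2, 0, 0), scale, sp),
    yy = .scale_derivative(arr, c(0, 2, 0), scale, sp),
    zz = .scale_derivative(arr, c(0, 0, 2), scale, sp),
    xy = .scale_derivative(arr, c(1, 1, 0), scale, sp),
    xz = .scale_derivative(arr, c(1, 0, 1), scale, sp),
    yz = .scale_derivative(arr, c(0, 1, 1), scale, sp))
  ev <- sym3_eigenvalues(as.vector(h$xx), as.vector(h$yy), as.vector(h$zz),
                         as.vector(h$xy), as.vector(h$xz), as.vector(h$yz))
  d <- dim(arr)
  list(l1 = array(ev[, 1], d), l2 = array(ev[, 2], d),
       l3 = array(ev[, 3], d))
}

#' Vesselness filter parameters
#'
#' @param alpha Plate-vs-line sensitivity (> 0), default 0.5.
#' @param beta Blob sensitivity (> 0), default 0.5.
#' @param c Structureness constant: a positive number, or `"auto"` for half
#'   the maximum Hessian Frobenius norm at each scale.
#' @param polarity `"bright"` (lumen brighter than background) or `"dark"`.
#' @return An object of class `vesselness_params`.
#' @export
vesselness_params <- function(alpha = 0.5, beta = 0.5, c = "auto",
                              polarity = c("bright", "dark")) {
  polarity <- match.arg(polarity)
  stopifnot(alpha > 0, beta > 0)
  if (!identical(c, "auto")) stopifnot(is.numeric(c), c > 0)
  structure(list(alpha = alpha, beta = beta, c = c, polarity = polarity),
            class = "vesselness_params")
}

#' Single-scale tubularity response from Hessian eigenvalues
#'
#' The classic three-factor Hessian vesselness: with eigenvalues sorted by
#' magnitude, the ratios `RA = |l2|/|l3|` (line vs plate), `RB =
#' |l1|/sqrt(|l2 l3|)` (line vs blob) and the structureness `S =
#' sqrt(l1^2+l2^2+l3^2)` combine as
#' `(1-exp(-RA^2/2a^2)) * exp(-RB^2/2b^2) * (1-exp(-S^2/2c^2))`.
#' The response is zero wherever the eigenvalue signs contradict the
#' polarity (bright lumen requires `l2 < 0` and `l3 < 0`; dark the reverse).
#'
#' @param eigenvalues Result of [hessian_eigenvalues()].
#' @param params A [vesselness_params].
#' @return Array of responses in `[0, 1]`.
#' @export
frangi_response <- function(eigenvalues, params = vesselness_params()) {
  l1 <- eigenvalues$l1; l2 <- eigenvalues$l2; l3 <- eigenvalues$l3
  S <- sqrt(l1^2 + l2^2 + l3^2)
  cpar <- if (identical(params$c, "auto")) max(S) / 2 else params$c
  if (cpar <= 0) cpar <- .Machine$double.eps
  a3 <- abs(l3)
  ok <- a3 > .Machine$double.eps * max(a3, 1)
  ra <- ifelse(ok, abs(l2) / pmax(a3, .Machine$double.xmin), 0)
  rb <- ifelse(ok, abs(l1) / sqrt(pmax(abs(l2) * a3, .Machine$double.xmin)), 0)
  v <- (1 - exp(-ra^2 / (2 * params$alpha^2))) *
    exp(-rb^2 / (2 * params$beta^2)) *
    (1 - exp(-S^2 / (2 * cpar^2)))
  gate <- if (params$polarity == "bright") l2 < 0 & l3 < 0 else l2 > 0 & l3 > 0
  v[!gate | !ok] <- 0
  v
}

#' Multi-scale vesselness map
#'
#' Computes the tubularity response at each scale of the scale set and takes
#' the per-voxel maximum, recording the winning scale.
#'
#' @param volume A [volume_image].
#' @param scales Ascending vector of Gaussian sigmas in mm (e.g. `c(4, 6)`).
#' @param params A [vesselness_params].
#' @return An object of class `vesselness_map`: `response` in `[0,1]`,
#'   `argmax_scale` (mm), and the source geometry.
#' @export
multiscale_vesselness <- function(volume, scales = c(4, 6),
                                  params = vesselness_params()) {
  stopifnot(inherits(volume, "volume_image"))
  scales <- as.numeric(scales)
  if (length(scales) == 0 || any(scales <= 0) ||
      any(diff(scales) <= 0) && length(scales) > 1)
    stop("scales must be non-empty, strictly positive and strictly increasing")
  resp <- NULL
  argmax <- NULL
  for (s in scales) {
    v <- frangi_response(hessian_eigenvalues(volume, s), params)
    if (is.null(resp)) {
      resp <- v
      argmax <- array(s, dim = dim(v))
    } else {
      w <- v > resp
      resp[w] <- v[w]
      argmax[w] <- s
    }
  }
  structure(list(response = resp, argmax_scale = argmax,
                 spacing = volume$spacing, origin = volume$origin,
                 direction = volume$direction, scales = scales,
                 params = params),
            class = "vesselness_map")
}

#' @export
print.vesselness_map <- function(x, ...) {
  cat("vesselness_map:", paste(dim(x$response), collapse = " x "),
      "voxels, scales", paste(x$scales, collapse = ", "), "mm\n")
  cat("  response range:",
      paste(signif(range(x$response), 4), collapse = " .. "), "\n")
  invisible(x)
}
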