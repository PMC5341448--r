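#' 3D scalar volume with world-coordinate geometry
#'
#' A `volume_image` bundles a 3D intensity array with its physical geometry:
#' per-axis voxel size in mm, the world position of voxel `(0,0,0)` and a
#' 3x3 orthonormal direction matrix. All algorithms in this package work in
#' world millimetres, so anisotropic grids (e.g. thick-slice multi-slice
#' acquisitions) are handled transparently.
#'
#' Voxel indices are 0-based and refer to voxel centres, so the
#' voxel-to-world map is the exact affine
#' `world = origin + direction %*% (index * spacing)`.
#'
#' @param data 3D numeric array of intensities (all finite).
#' @param spacing Numeric length-3, voxel size in mm per axis (all > 0).
#' @param origin Numeric length-3, world position (mm) of voxel (0,0,0).
#' @param direction 3x3 orthonormal matrix mapping voxel axes to world axes.
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         direction = diag(3)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("data must be a 3D array")
  if (!all(is.finite(data)))
    stop("volume intensities must all be finite")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  direction <- as.matrix(direction)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be three finite values (mm)")
  if (!all(dim(direction) == c(3L, 3L)) ||
      max(abs(crossprod(direction) - diag(3))) > 1e-6)
    stop("direction must be a 3x3 orthonormal matrix")
  structure(list(data = data, spacing = spacing, origin = origin,
                 direction = direction),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  cat("volume_image:", paste(dim(x$data), collapse = " x "), "voxels\n")
  cat("  spacing (mm):", paste(signif(x$spacing, 4), collapse = ", "), "\n")
  cat("  origin  (mm):", paste(signif(x$origin, 4), collapse = ", "), "\n")
  cat("  intensity range:", paste(signif(range(x$data), 4), collapse = " .. "),
      "\n")
  invisible(x)
}

#' @export
dim.volume_image <- function(x) dim(x$data)

#' Convert fractional voxel indices to world coordinates
#'
#' @param volume A [volume_image].
#' @param index Numeric length-3 vector or n x 3 matrix of 0-based
#'   (possibly fractional) voxel indices.
#' @return World coordinates in mm: a length-3 vector or n x 3 matrix.
#' @export
voxel_to_world <- function(volume, index) {
  idx <- if (is.matrix(index)) index else matrix(index, nrow = 1)
  if (ncol(idx) != 3L || any(!is.finite(idx)))
    stop("index must be finite with three columns")
  w <- sweep(idx, 2, volume$spacing, `*`) %*% t(volume$direction)
  w <- sweep(w, 2, volume$origin, `+`)
  if (is.matrix(index)) w else drop(w)
}

#' Convert world coordinates (mm) to fractional voxel indices
#'
#' Exact inverse of [voxel_to_world()].
#'
#' @inheritParams voxel_to_world
#' @param world Length-3 vector or n x 3 matrix of world points in mm.
#' @return 0-based fractional voxel indices.
#' @export
world_to_voxel <- function(volume, world) {
  w <- if (is.matrix(world)) world else matrix(world, nrow = 1)
  if (ncol(w) != 3L || any(!is.finite(w)))
    stop("world must be finite with three columns")
  v <- sweep(w, 2, volume$origin, `-`) %*% volume$direction  # t(D^-1) = D
  v <- sweep(v, 2, volume$spacing, `/`)
  if (is.matrix(world)) v else drop(v)
}

#' Does a world point lie inside the volume grid?
#' @inheritParams voxel_to_world
#' @param world Length-3 world point (mm).
#' @return Logical.
#' @export
in_grid <- function(volume, world) {
  v <- world_to_voxel(volume, world)
  all(v >= 0 & v <= dim(volume$data) - 1)
}

#' Read a NIfTI-1 volume
#'
#' Geometry (spacing, origin, direction) is taken from the stored xform
#' affine; the world frame is used exactly as stored, with no RAS/LPS
#' reorientation.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A [volume_image].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path), error = function(e)
    stop("malformed NIfTI file (header/xform unreadable): ",
         conditionMessage(e)))
  arr <- as.array(img)
  arr <- array(as.numeric(arr), dim = dim(arr))  # strip header attributes
  if (length(dim(arr)) != 3L)
    stop("malformed NIfTI: field 'dim' does not describe a 3D volume (got ",
         length(dim(arr)), " dimensions)")
  aff <- RNifti::xform(img)
  m <- aff[1:3, 1:3]
  spacing <- sqrt(colSums(m^2))
  if (any(spacing <= 0) || any(!is.finite(spacing)))
    stop("malformed NIfTI: field 'pixdim'/xform implies non-positive spacing")
  direction <- sweep(m, 2, spacing, `/`)
  volume_image(arr, spacing = spacing, origin = aff[1:3, 4],
               direction = direction)
}

#' Write a volume as NIfTI-1
#'
#' @param volume A [volume_image].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "volume_image"))
  aff <- rbind(cbind(volume$direction %*% diag(volume$spacing),
                     volume$origin), c(0, 0, 0, 1))
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::`sform<-`(img, structure(aff, code = 2L)) -> img
  RNifti::`qform<-`(img, structure(aff, code = 2L)) -> img
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Acquisition-plane definition
#'
#' Describes a 2D acquisition or reformat plane (e.g. a phase-contrast flow
#' plane, or an oblique-sagittal view) by a point on the plane, its unit
#' normal, and two orthonormal in-plane axes.
#'
#' @param point Length-3 world point on the plane (mm).
#' @param normal Length-3 plane normal (normalised internally).
#' @param in_plane_axes Optional 2 x 3 matrix of in-plane axes; constructed
#'   automatically when omitted.
#' @return An object of class `plane_def`.
#' @export
plane_def <- function(point, normal, in_plane_axes = NULL) {
  point <- as.numeric(point)
  normal <- as.numeric(normal)
  if (length(point) != 3L || any(!is.finite(point)))
    stop("point must be a finite 3-vector")
  nn <- sqrt(sum(normal^2))
  if (length(normal) != 3L || !is.finite(nn) || nn == 0)
    stop("normal must be a nonzero 3-vector")
  normal <- normal / nn
  if (is.null(in_plane_axes)) {
    ref <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u <- ref - sum(ref * normal) * normal
    u <- u / sqrt(sum(u^2))
    v <- c(normal[2] * u[3] - normal[3] * u[2],
           normal[3] * u[1] - normal[1] * u[3],
           normal[1] * u[2] - normal[2] * u[1])
    in_plane_axes <- rbind(u, v)
    dimnames(in_plane_axes) <- NULL
  } else {
    in_plane_axes <- as.matrix(in_plane_axes)
    if (!all(dim(in_plane_axes) == c(2L, 3L)))
      stop("in_plane_axes must be a 2 x 3 matrix")
    g <- in_plane_axes %*% cbind(normal)
    if (max(abs(g)) > 1e-9 ||
        abs(sum(in_plane_axes[1, ] * in_plane_axes[2, ])) > 1e-9 ||
        max(abs(rowSums(in_plane_axes^2) - 1)) > 1e-9)
      stop("in_plane_axes must be unit length, mutually orthogonal and ",
           "orthogonal to the normal")
  }
  dimnames(in_plane_axes) <- NULL
  structure(list(point = point, normal = normal,
                 in_plane_axes = in_plane_axes),
            class = "plane_def")
}

#' @export
print.plane_def <- function(x, ...) {
  cat("plane_def: point (", paste(signif(x$point, 4), collapse = ", "),
      ") mm, normal (", paste(signif(x$normal, 4), collapse = ", "), ")\n",
      sep = "")
  invisible(x)
}

#' Read a plane definition from JSON
#'
#' Expects `{"point":[x,y,z],"normal":[nx,ny,nz]}` in mm.
#'
#' @param path JSON file path.
#' @return A [plane_def].
#' @export
read_plane_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$point) || is.null(obj$normal))
    stop("plane JSON must contain 'point' and 'normal'")
  plane_def(obj$point, obj$normal)
}

#' Write a plane definition to JSON
#' @param plane A [plane_def].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_plane_json <- function(plane, path) {
  jsonlite::write_json(list(point = plane$point, normal = plane$normal),
                       path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
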