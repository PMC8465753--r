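#' Volume geometry
#'
#' Describes the sampling grid shared by all volumes of one case: lattice
#' shape (voxels), voxel spacing (mm), and the affine mapping 0-based voxel
#' indices to world coordinates (mm). World coordinates refer to voxel
#' centres. The default affine is axis-aligned and centres the lattice on
#' the world origin, so the mid-sagittal plane x = 0 bisects the volume --
#' the convention of the symmetric reference template the atlas bundle
#' lives in.
#'
#' @param shape integer vector of length 3, lattice dimensions (> 0).
#' @param spacing numeric vector of length 3, voxel size in mm (> 0).
#' @param affine optional 4x4 voxel-to-world affine (0-based indices).
#'   When omitted, `diag(spacing)` with a centering translation is used.
#' @return an object of class `volume_geometry` with fields `shape`,
#'   `spacing`, `affine`.
#' @export
volume_geometry <- function(shape, spacing = c(1, 1, 1), affine = NULL) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape <= 0L))
    stop("'shape' must be 3 positive integers")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 positive reals (mm)")
  if (is.null(affine)) {
    affine <- diag(4)
    diag(affine)[1:3] <- spacing
    affine[1:3, 4] <- -(shape - 1) / 2 * spacing
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || any(!is.finite(affine)))
    stop("'affine' must be a finite 4x4 matrix")
  det_a <- det(affine[1:3, 1:3])
  if (!is.finite(det_a) || abs(det_a) < .Machine$double.eps)
    stop("'affine' must be invertible")
  col_norms <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(abs(col_norms - spacing) > 1e-3))
    stop("'spacing' inconsistent with affine column norms (tolerance 1e-3 mm)")
  structure(list(shape = shape, spacing = spacing, affine = affine),
            class = "volume_geometry")
}

#' @export
print.volume_geometry <- function(x, ...) {
  cat(sprintf("<volume_geometry> %d x %d x %d voxels, spacing %.4g x %.4g x %.4g mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Voxel volume in mm^3
#' @param geometry a `volume_geometry`.
#' @return scalar voxel volume (mm^3).
#' @export
voxel_volume_mm3 <- function(geometry) prod(geometry$spacing)

#' Map 0-based voxel indices to world coordinates (mm)
#'
#' @param geometry a `volume_geometry`.
#' @param idx numeric matrix (n x 3) of 0-based voxel indices.
#' @return n x 3 matrix of world coordinates, mm.
#' @export
voxel_to_world <- function(geometry, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3)
  h <- cbind(idx, 1)
  out <- h %*% t(geometry$affine)
  out[, 1:3, drop = FALSE]
}

#' Map world coordinates (mm) to continuous 0-based voxel indices
#' @param geometry a `volume_geometry`.
#' @param xyz numeric matrix (n x 3) of world coordinates.
#' @return n x 3 matrix of continuous voxel indices (0-based).
#' @export
world_to_voxel <- function(geometry, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  h <- cbind(xyz, 1)
  out <- h %*% t(solve(geometry$affine))
  out[, 1:3, drop = FALSE]
}

#' Test two geometries for equality
#' @param a,b `volume_geometry` objects.
#' @param tol numeric tolerance on spacing and affine entries.
#' @return logical.
#' @export
same_geometry <- function(a, b, tol = 1e-5) {
  all(a$shape == b$shape) &&
    all(abs(a$spacing - b$spacing) <= tol) &&
    all(abs(a$affine - b$affine) <= tol)
}

stop_if_geometry_mismatch <- function(a, b) {
  if (!same_geometry(a$geometry, b$geometry))
    stop("operands must share the same geometry")
  invisible(TRUE)
}

#' Binary mask on a geometry
#'
#' @param voxels logical (or coercible) array matching `geometry$shape`.
#' @param geometry a `volume_geometry`.
#' @return an object of class `binary_mask` with fields `geometry`, `voxels`.
#' @export
binary_mask <- function(voxels, geometry) {
  voxels <- array(as.logical(voxels), dim = geometry$shape)
  if (any(is.na(voxels))) stop("mask voxels must not contain NA")
  structure(list(geometry = geometry, voxels = voxels), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d foreground of %d voxels (%.3f mL)\n",
              sum(x$voxels), length(x$voxels),
              sum(x$voxels) * voxel_volume_mm3(x$geometry) / 1000))
  invisible(x)
}

#' Probability map on a geometry
#'
#' @param values numeric array in [0, 1] matching `geometry$shape`.
#' @param geometry a `volume_geometry`.
#' @return an object of class `probability_map` with fields `geometry`,
#'   `values`.
#' @export
probability_map <- function(values, geometry) {
  values <- array(as.numeric(values), dim = geometry$shape)
  if (any(!is.finite(values))) stop("probability values must be finite")
  if (any(values < 0 | values > 1)) stop("probability values must lie in [0, 1]")
  structure(list(geometry = geometry, values = values),
            class = "probability_map")
}

#' @export
print.probability_map <- function(x, ...) {
  cat(sprintf("<probability_map> %d x %d x %d, range [%.3f, %.3f]\n",
              x$geometry$shape[1], x$geometry$shape[2], x$geometry$shape[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' Binarize a probability map at a threshold
#'
#' Voxels with probability >= `threshold` become foreground (inclusive
#' comparison).
#'
#' @param map a `probability_map`.
#' @param threshold scalar in [0, 1].
#' @return a `binary_mask`.
#' @export
binarize <- function(map, threshold) {
  binary_mask(map$values >= threshold, map$geometry)
}

# 0-based index matrix of foreground voxels.
mask_indices <- function(mask) {
  which(mask$voxels, arr.ind = TRUE) - 1
}

# World coordinates (mm) of foreground voxel centres.
mask_world_coords <- function(mask) {
  idx <- mask_indices(mask)
  if (nrow(idx) == 0L) return(matrix(numeric(0), ncol = 3))
  voxel_to_world(mask$geometry, idx)
}
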