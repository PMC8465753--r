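#' Dice similarity coefficient
#'
#' Volume-overlap similarity 2|A n B| / (|A| + |B|). Two empty masks agree
#' on absence and score 1.0; an empty versus a non-empty mask scores 0.0.
#'
#' @param a,b `binary_mask` objects on the same geometry.
#' @return scalar in [0, 1].
#' @export
dice <- function(a, b) {
  stop_if_geometry_mismatch(a, b)
  na <- sum(a$voxels); nb <- sum(b$voxels)
  if (na + nb == 0L) return(1.0)
  2 * sum(a$voxels & b$voxels) / (na + nb)
}

# Surface voxels: foreground voxels with at least one 6-neighbour that is
# background or outside the lattice.
surface_mask <- function(mask) {
  off <- matrix(c(1, 0, 0, -1, 0, 0, 0, 1, 0, 0, -1, 0, 0, 0, 1, 0, 0, -1),
                ncol = 3, byrow = TRUE)
  eroded <- cpp_erode(as.vector(mask$voxels), mask$geometry$shape,
                      rbind(c(0L, 0L, 0L), off))
  binary_mask(mask$voxels & !array(eroded, dim = mask$geometry$shape),
              mask$geometry)
}

directed_p95 <- function(from_coords, to_coords) {
  d <- cpp_min_dists(from_coords, to_coords)
  as.numeric(stats::quantile(d, 0.95))
}

#' 95th-percentile Hausdorff distance (mm)
#'
#' Boundary-delineation distance between two masks: for each direction the
#' 95th percentile of surface-voxel nearest distances is taken, and the
#' symmetric value is the maximum of the two directed percentiles.
#' Distances are Euclidean in world millimetres. Undefined when either
#' mask is empty; `NA_real_` is returned so callers can decide sentinel
#' handling.
#'
#' @param a,b `binary_mask` objects on the same geometry.
#' @return distance in mm, or `NA_real_` if either mask is empty.
#' @export
hd95 <- function(a, b) {
  stop_if_geometry_mismatch(a, b)
  if (!any(a$voxels) || !any(b$voxels)) return(NA_real_)
  sa <- mask_world_coords(surface_mask(a))
  sb <- mask_world_coords(surface_mask(b))
  max(directed_p95(sa, sb), directed_p95(sb, sa))
}

#' Minimum surface distance between two masks (mm)
#'
#' Minimum Euclidean world distance between any foreground voxel centre of
#' `a` and any of `b`; 0 when the masks overlap.
#'
#' @param a,b non-empty `binary_mask` objects on the same geometry.
#' @return distance in mm.
#' @export
min_surface_distance <- function(a, b) {
  stop_if_geometry_mismatch(a, b)
  if (!any(a$voxels) || !any(b$voxels))
    stop("min_surface_distance requires two non-empty masks")
  if (any(a$voxels & b$voxels)) return(0.0)
  sa <- mask_world_coords(surface_mask(a))
  sb <- mask_world_coords(surface_mask(b))
  min(cpp_min_dists(sa, sb))
}
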