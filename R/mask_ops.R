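#' Connected components of a binary mask
#'
#' Labels the stand-alone foreground objects of a 3D mask under the chosen
#' voxel neighbourhood. Labels are contiguous 1..K in raster order of each
#' component's first voxel; 0 is background.
#'
#' @param mask a `binary_mask`.
#' @param connectivity 6, 18 or 26 (default 26, the standard neighbourhood
#'   for 3D lesion analysis).
#' @return an object of class `labeled_components` with fields `geometry`,
#'   `labels` (integer array), `sizes` (voxel count per label) and
#'   `connectivity`.
#' @export
connected_components <- function(mask, connectivity = 26) {
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("'connectivity' must be one of 6, 18, 26")
  lab <- cpp_label_components(as.vector(mask$voxels), mask$geometry$shape,
                              connectivity)
  k <- attr(lab, "n_components")
  labels <- array(as.integer(lab), dim = mask$geometry$shape)
  sizes <- if (k > 0L) tabulate(labels[labels > 0L], nbins = k) else integer(0)
  structure(list(geometry = mask$geometry, labels = labels,
                 sizes = sizes, connectivity = connectivity),
            class = "labeled_components")
}

#' @export
print.labeled_components <- function(x, ...) {
  cat(sprintf("<labeled_components> %d component(s), %d-connectivity\n",
              length(x$sizes), x$connectivity))
  if (length(x$sizes))
    cat("  sizes (voxels):", paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}

# Extract one labelled component as a binary_mask.
component_mask <- function(components, label) {
  binary_mask(components$labels == label, components$geometry)
}

# Structuring-element offsets: ball of voxel offsets with Euclidean
# index norm <= radius.
ball_offsets <- function(radius) {
  r <- as.integer(ceiling(radius))
  g <- expand.grid(x = -r:r, y = -r:r, z = -r:r)
  g <- g[g$x^2 + g$y^2 + g$z^2 <= radius^2, , drop = FALSE]
  as.matrix(g)
}

#' Morphological binary closing with a spherical kernel
#'
#' Closing fills gaps and slits narrower than the kernel. The structuring
#' element is the ball of voxel offsets with Euclidean norm at most
#' `radius_voxels`. With `iterations = n`, the mask is dilated n times and
#' then eroded n times. The lattice is zero-padded by
#' `radius_voxels * iterations` on every side before the operation and
#' cropped afterwards, so closing is extensive: it never removes
#' foreground voxels, including at the volume border.
#'
#' @param mask a `binary_mask`.
#' @param radius_voxels kernel radius in voxels (default 2).
#' @param iterations number of dilation (then erosion) passes (default 1).
#' @return the closed `binary_mask` on the original geometry.
#' @export
binary_closing <- function(mask, radius_voxels = 2, iterations = 1) {
  if (radius_voxels <= 0 || iterations < 1)
    stop("'radius_voxels' and 'iterations' must be positive")
  if (!any(mask$voxels)) return(mask)
  off <- ball_offsets(radius_voxels)
  pad <- as.integer(ceiling(radius_voxels) * iterations)
  shp <- mask$geometry$shape
  padded_shape <- shp + 2L * pad
  work <- array(FALSE, dim = padded_shape)
  work[pad + seq_len(shp[1]), pad + seq_len(shp[2]), pad + seq_len(shp[3])] <-
    mask$voxels
  v <- as.vector(work)
  for (i in seq_len(iterations)) v <- cpp_dilate(v, padded_shape, off)
  for (i in seq_len(iterations)) v <- cpp_erode(v, padded_shape, off)
  work <- array(v, dim = padded_shape)
  out <- work[pad + seq_len(shp[1]), pad + seq_len(shp[2]), pad + seq_len(shp[3])]
  binary_mask(out, mask$geometry)
}

#' Resample a mask onto a target geometry (nearest neighbour)
#'
#' Each target voxel centre is mapped to world coordinates, then into the
#' source lattice; the nearest source voxel supplies the value. Target
#' voxels falling outside the source lattice become background. This is a
#' plain resampling utility for masks that already live in a shared world
#' frame; it performs no registration.
#'
#' @param mask a `binary_mask`.
#' @param target a `volume_geometry`.
#' @return a `binary_mask` on `target`.
#' @export
resample_to_geometry <- function(mask, target) {
  shp <- target$shape
  idx <- as.matrix(expand.grid(x = seq_len(shp[1]) - 1,
                               y = seq_len(shp[2]) - 1,
                               z = seq_len(shp[3]) - 1))
  world <- voxel_to_world(target, idx)
  src <- round(world_to_voxel(mask$geometry, world))
  sshp <- mask$geometry$shape
  inb <- src[, 1] >= 0 & src[, 1] < sshp[1] &
         src[, 2] >= 0 & src[, 2] < sshp[2] &
         src[, 3] >= 0 & src[, 3] < sshp[3]
  out <- logical(nrow(src))
  if (any(inb)) {
    lin <- src[inb, 1] + sshp[1] * (src[inb, 2] + sshp[2] * src[inb, 3]) + 1
    out[inb] <- as.vector(mask$voxels)[lin]
  }
  binary_mask(array(out, dim = shp), target)
}
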