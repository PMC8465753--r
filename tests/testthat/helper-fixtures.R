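# Shared small fixtures, built in code.

iso_geom <- function(shape = c(12, 12, 12), spacing = c(1, 1, 1)) {
  volume_geometry(shape, spacing)
}

mask_from_indices <- function(geom, idx1) {
  arr <- array(FALSE, dim = geom$shape)
  arr[idx1] <- TRUE
  binary_mask(arr, geom)
}

# Solid cube [lo, hi] (1-based inclusive) as a mask.
cube_mask <- function(geom, lo, hi) {
  arr <- array(FALSE, dim = geom$shape)
  arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  binary_mask(arr, geom)
}

# Solid voxelized sphere around a world centre.
sphere_mask <- function(geom, centre, radius_mm) {
  shp <- geom$shape
  idx <- as.matrix(expand.grid(x = seq_len(shp[1]) - 1, y = seq_len(shp[2]) - 1,
                               z = seq_len(shp[3]) - 1))
  w <- voxel_to_world(geom, idx)
  d <- sqrt(rowSums((w - matrix(centre, nrow(w), 3, byrow = TRUE))^2))
  binary_mask(array(d <= radius_mm, dim = shp), geom)
}

# A small cached test bundle (building one is the expensive part of the
# feature tests; 32^3 keeps it quick).
test_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_bundle(volume_geometry(c(32, 36, 32)), seed = 42)
    cache
  }
})
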