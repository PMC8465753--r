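#' Refine a tumor segmentation mask
#'
#' Removes segmentation noise before feature extraction: a binary closing
#' with a spherical kernel (radius 2 voxels) applied with two iterations,
#' followed by removal of connected components smaller than 0.1 mL. The
#' volume threshold is strict ("smaller than"), so a component of exactly
#' 0.1 mL is kept. May return an empty mask.
#'
#' @param mask a `binary_mask` in the reference space.
#' @param closing_radius kernel radius in voxels (default 2).
#' @param closing_iterations dilation/erosion passes (default 2).
#' @param min_volume_ml minimum component volume kept, mL (default 0.1).
#' @param connectivity component connectivity (default 26).
#' @return the refined `binary_mask`.
#' @export
refine_tumor_mask <- function(mask, closing_radius = 2,
                              closing_iterations = 2,
                              min_volume_ml = 0.1, connectivity = 26) {
  closed <- binary_closing(mask, closing_radius, closing_iterations)
  comps <- connected_components(closed, connectivity)
  if (length(comps$sizes) == 0L) return(closed)
  vox_ml <- voxel_volume_mm3(mask$geometry) / 1000
  keep <- which(comps$sizes * vox_ml >= min_volume_ml)
  binary_mask(array(comps$labels %in% keep, dim = mask$geometry$shape),
              mask$geometry)
}

#' Tumor volume in millilitres
#'
#' Product of the voxel count and the voxel volume (spacing product, mm^3),
#' expressed in mL.
#'
#' @param mask a `binary_mask`.
#' @return volume in mL.
#' @export
compute_volume <- function(mask) {
  sum(mask$voxels) * voxel_volume_mm3(mask$geometry) / 1000
}

#' Tumor laterality
#'
#' Percentage of the tumor volume overlapping each hemisphere, and whether
#' the tumor crosses the midline (at least one voxel strictly in each
#' hemisphere).
#'
#' @param mask a non-empty `binary_mask`.
#' @param hemisphere a `hemisphere_mask` on the same geometry.
#' @return list with `left_pct`, `right_pct` (summing to 100) and
#'   `midline_crossing` (logical).
#' @export
compute_laterality <- function(mask, hemisphere) {
  stop_if_geometry_mismatch(mask, hemisphere)
  n <- sum(mask$voxels)
  if (n == 0L) stop("laterality is undefined for an empty mask")
  n_left <- sum(mask$voxels & hemisphere$left)
  n_right <- n - n_left
  list(left_pct = 100 * n_left / n,
       right_pct = 100 * n_right / n,
       midline_crossing = n_left >= 1L && n_right >= 1L)
}

#' Multifocality analysis
#'
#' Detects stand-alone tumor foci by connected components, identifies the
#' biggest focus by volume, and counts as independent satellites only
#' those foci at least `min_distance_mm` (5.0 mm) away from the biggest.
#' Closer components are not taken into consideration for the focus count
#' or the distance (they still belong to the tumor for volume and overlap
#' purposes). The reported distance is the largest minimum distance
#' between the biggest focus and any qualifying satellite; -1.0 mm is
#' reported for a unifocal tumor.
#'
#' @param mask a non-empty `binary_mask`.
#' @param min_distance_mm satellite qualification distance (default 5.0).
#' @param connectivity component connectivity (default 26).
#' @return list with `multifocal` (logical), `focus_count` (integer),
#'   `satellite_distance_mm`, and auxiliary `foci` (per-component volume
#'   in mL and equivalent-sphere diameter in mm, with the biggest flagged).
#' @export
compute_multifocality <- function(mask, min_distance_mm = 5.0,
                                  connectivity = 26) {
  comps <- connected_components(mask, connectivity)
  k <- length(comps$sizes)
  if (k == 0L) stop("multifocality is undefined for an empty mask")
  vox_ml <- voxel_volume_mm3(mask$geometry) / 1000
  vol_ml <- comps$sizes * vox_ml
  # equivalent-sphere diameter from volume: d = 2 * (3V / 4pi)^(1/3), mm
  diam_mm <- 2 * (3 * vol_ml * 1000 / (4 * pi))^(1 / 3)
  biggest <- which.max(vol_ml)
  foci <- data.frame(label = seq_len(k), volume_ml = vol_ml,
                     diameter_mm = diam_mm, biggest = seq_len(k) == biggest)
  if (k == 1L)
    return(list(multifocal = FALSE, focus_count = 1L,
                satellite_distance_mm = -1.0, foci = foci))
  big_mask <- component_mask(comps, biggest)
  dists <- vapply(setdiff(seq_len(k), biggest), function(lbl)
    min_surface_distance(component_mask(comps, lbl), big_mask), numeric(1))
  qualifying <- dists[dists >= min_distance_mm]
  focus_count <- 1L + length(qualifying)
  list(multifocal = focus_count > 1L,
       focus_count = focus_count,
       satellite_distance_mm = if (length(qualifying)) max(qualifying) else -1.0,
       foci = foci)
}

#' Expected resectability
#'
#' Integrates the resection-probability heat map of the dominant
#' hemisphere (the one with the higher tumor overlap percentage) over the
#' tumor voxels. The expected resectable volume is the probability sum
#' times the voxel volume; the expected residual volume is the tumor
#' volume minus the resectable volume; the resectability index is the
#' resectable fraction, in [0, 1] (0 = nonresectable, 1 = completely
#' resectable).
#'
#' @param mask a non-empty `binary_mask`.
#' @param heatmap a `resection_heatmap` on the same geometry.
#' @param laterality result of [compute_laterality()] for `mask`; ties go
#'   to the left hemisphere.
#' @return list with `expected_residual_ml`, `resectability_index` and
#'   auxiliary `expected_resectable_ml`.
#' @export
compute_resectability <- function(mask, heatmap, laterality) {
  stop_if_geometry_mismatch(mask, heatmap)
  if (!any(mask$voxels)) stop("resectability is undefined for an empty mask")
  hm <- if (laterality$left_pct >= laterality$right_pct)
    heatmap$left_map else heatmap$right_map
  vox_ml <- voxel_volume_mm3(mask$geometry) / 1000
  tumor_ml <- sum(mask$voxels) * vox_ml
  resectable_ml <- sum(hm[mask$voxels]) * vox_ml
  list(expected_residual_ml = tumor_ml - resectable_ml,
       resectability_index = resectable_ml / tumor_ml,
       expected_resectable_ml = resectable_ml)
}

#' Cortical location profile
#'
#' For every structure of each cortical parcellation, the percentage of
#' the tumor volume overlapping the structure: 100 * |tumor n structure| /
#' |tumor|. 87 named values across the four atlases.
#'
#' @param mask a non-empty `binary_mask`.
#' @param cortical named list of the four `parcellation_atlas` objects.
#' @return named numeric vector of 87 percentages, names
#'   `cortical.<atlas>.<structure>`.
#' @export
cortical_profile <- function(mask, cortical) {
  if (!any(mask$voxels)) stop("location profile is undefined for an empty mask")
  n <- sum(mask$voxels)
  out <- numeric(0)
  for (id in names(cortical)) {
    a <- cortical[[id]]
    stop_if_geometry_mismatch(mask, a)
    tumor_labels <- a$labels[mask$voxels]
    counts <- tabulate(tumor_labels[tumor_labels > 0L],
                       nbins = max(as.integer(names(a$names))))
    pct <- vapply(names(a$names), function(lbl) {
      i <- as.integer(lbl)
      100 * (if (i <= length(counts)) counts[i] else 0L) / n
    }, numeric(1))
    names(pct) <- sprintf("cortical.%s.%s", id, unname(a$names))
    out <- c(out, pct)
  }
  out
}

#' Subcortical location profile
#'
#' For every structure of the probabilistic subcortical atlas
#' (binarized at its threshold, 0.5 by default): the overlap percentage as
#' in [cortical_profile()], and a tumor-to-structure distance in mm. The
#' distance is 0.0 for overlapping structures; otherwise the directed
#' 95th-percentile distance from the tumor boundary voxels to the
#' structure mask. Structures that are empty after thresholding get the
#' sentinel distance -1.0.
#'
#' @param mask a non-empty `binary_mask`.
#' @param atlas a `probabilistic_atlas`.
#' @return list of two named numeric vectors of length 68: `overlap_pct`
#'   and `distance_mm`.
#' @export
subcortical_profile <- function(mask, atlas) {
  stop_if_geometry_mismatch(mask, atlas)
  n <- sum(mask$voxels)
  if (n == 0L) stop("location profile is undefined for an empty mask")
  tumor_surface <- mask_world_coords(surface_mask(mask))
  nm <- names(atlas$structures)
  overlap <- stats::setNames(numeric(length(nm)), nm)
  dist <- stats::setNames(numeric(length(nm)), nm)
  for (s in nm) {
    smask <- atlas$structures[[s]] >= atlas$threshold
    if (!any(smask)) {
      overlap[s] <- 0
      dist[s] <- -1.0
      next
    }
    inter <- sum(smask & mask$voxels)
    overlap[s] <- 100 * inter / n
    if (inter > 0L) {
      dist[s] <- 0.0
    } else {
      scoords <- voxel_to_world(mask$geometry,
                                which(smask, arr.ind = TRUE) - 1)
      dist[s] <- directed_p95(tumor_surface, scoords)
    }
  }
  list(overlap_pct = overlap, distance_mm = dist)
}
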