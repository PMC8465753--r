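# Seeded synthetic phantoms and atlas bundles. Everything here is a pure
# function of (spec, seed): the generators emulate the *structure* of the
# reference-space data (hemisphere split, disjoint parcellations with the
# canonical structure counts, probabilistic subcortical structures,
# per-hemisphere resection gradients, spherical tumor phantoms), not the
# anatomy or intensity statistics of real MRI.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Near-cubic factor triple a*b*c = k, a >= b >= c.
factor_triple <- function(k) {
  best <- c(k, 1, 1)
  for (a in 1:k) {
    if (k %% a != 0) next
    rest <- k / a
    for (b in 1:rest) {
      if (rest %% b != 0) next
      tri <- sort(c(a, b, rest / b), decreasing = TRUE)
      if (tri[1] / tri[3] < best[1] / best[3]) best <- tri
    }
  }
  best
}

# Tile an index box [lo, hi] (1-based, inclusive) into k disjoint boxes.
tile_region <- function(lo, hi, k) {
  ext <- hi - lo + 1
  tri <- factor_triple(k)
  ax <- order(ext, decreasing = TRUE)           # largest factor on longest axis
  nsplit <- integer(3)
  nsplit[ax] <- tri
  cuts <- lapply(1:3, function(d) {
    b <- floor(seq(lo[d] - 1, hi[d], length.out = nsplit[d] + 1))
    cbind(b[-length(b)] + 1, b[-1])
  })
  boxes <- list()
  for (i in seq_len(nsplit[1]))
    for (j in seq_len(nsplit[2]))
      for (l in seq_len(nsplit[3]))
        boxes[[length(boxes) + 1]] <-
          rbind(c(cuts[[1]][i, 1], cuts[[2]][j, 1], cuts[[3]][l, 1]),
                c(cuts[[1]][i, 2], cuts[[2]][j, 2], cuts[[3]][l, 2]))
  boxes
}

# World coordinates of every voxel centre, rows in array order.
all_world_coords <- function(geometry) {
  shp <- geometry$shape
  idx <- as.matrix(expand.grid(x = seq_len(shp[1]) - 1,
                               y = seq_len(shp[2]) - 1,
                               z = seq_len(shp[3]) - 1))
  voxel_to_world(geometry, idx)
}

#' Generate a synthetic atlas bundle
#'
#' Builds a complete, internally consistent reference-space bundle from a
#' seed: the hemisphere mask split at world x = 0; four disjoint
#' box-tiled cortical parcellations with the canonical structure counts
#' (15, 48, 7, 17); a probabilistic subcortical atlas of 68 structures
#' (28 mirrored left/right pairs plus 12 midline structures, 40 unique
#' base names) with linear radial probability profiles
#' p = max(0, 1 - d/r); and per-hemisphere resection heat maps with a
#' radial gradient decaying from each hemisphere's centroid. Identical
#' seeds give identical bundles.
#'
#' @param geometry a `volume_geometry` (default 48 x 56 x 48 at 1 mm).
#' @param seed integer seed.
#' @return an `atlas_bundle`.
#' @export
generate_bundle <- function(geometry = volume_geometry(c(48, 56, 48)),
                            seed = 1) {
  shp <- geometry$shape
  if (any(shp < 24L))
    stop("geometry too small to host the atlas structure counts (need >= 24 voxels per axis)")
  with_seed(seed, {
    hemi <- hemisphere_from_geometry(geometry)
    world <- all_world_coords(geometry)

    margin <- 4L
    lo <- rep(margin + 1L, 3)
    hi <- shp - margin
    counts <- c("MNI-structural" = 15L, "Harvard-Oxford" = 48L,
                "Schaefer7" = 7L, "Schaefer17" = 17L)
    cortical <- lapply(names(counts), function(id) {
      k <- counts[[id]]
      boxes <- tile_region(lo, hi, k)
      labels <- array(0L, dim = shp)
      for (i in seq_len(k)) {
        b <- boxes[[i]]
        labels[b[1, 1]:b[2, 1], b[1, 2]:b[2, 2], b[1, 3]:b[2, 3]] <- i
      }
      nm <- stats::setNames(sprintf("%s_area_%02d", gsub("-", "_", id),
                                    seq_len(k)), seq_len(k))
      parcellation_atlas(labels, nm, id, geometry)
    })
    names(cortical) <- names(counts)

    # Subcortical structures: mirrored pairs in x, plus midline singletons.
    half_extent <- abs(voxel_to_world(geometry, rbind(c(0, 0, 0)))[1, ])
    r_range <- c(5, 9)                          # profile radius, mm
    centre_box <- function(side) {
      # side = -1 left, +1 right, 0 midline; margins keep p >= 0.5 inside
      m <- r_range[2] / 2 + 2
      x <- if (side == 0) 0 else side * stats::runif(1, m, half_extent[1] - m)
      c(x, stats::runif(1, -(half_extent[2] - m), half_extent[2] - m),
        stats::runif(1, -(half_extent[3] - m), half_extent[3] - m))
    }
    radial <- function(centre, r) {
      d <- sqrt((world[, 1] - centre[1])^2 + (world[, 2] - centre[2])^2 +
                (world[, 3] - centre[3])^2)
      array(pmax(0, 1 - d / r), dim = shp)
    }
    structures <- list()
    for (i in 1:28) {
      c_l <- centre_box(-1)
      r <- stats::runif(1, r_range[1], r_range[2])
      structures[[sprintf("tract_%02d_left", i)]] <- radial(c_l, r)
      structures[[sprintf("tract_%02d_right", i)]] <-
        radial(c_l * c(-1, 1, 1), r)
    }
    for (i in 1:12) {
      structures[[sprintf("commissural_%02d", i)]] <-
        radial(centre_box(0), stats::runif(1, r_range[1], r_range[2]))
    }
    subcortical <- probabilistic_atlas(structures, geometry)

    # Resection heat maps: probability decays linearly with distance from
    # each hemisphere's centroid, scaled so the far edge reaches ~0.1.
    hemi_map <- function(left) {
      sel <- if (left) hemi$left else !hemi$left
      centroid <- colMeans(world[as.vector(sel), , drop = FALSE])
      d <- sqrt((world[, 1] - centroid[1])^2 + (world[, 2] - centroid[2])^2 +
                (world[, 3] - centroid[3])^2)
      scale <- max(d[as.vector(sel)])
      array(pmin(1, pmax(0, 1 - 0.9 * d / scale)), dim = shp)
    }
    heatmap <- resection_heatmap(hemi_map(TRUE), hemi_map(FALSE), geometry)

    atlas_bundle(hemi, cortical, subcortical, heatmap)
  })
}

#' Phantom specification
#'
#' Describes a multi-focal spherical tumor phantom: focus centres in
#' world mm, radii in mm, the rater boundary-noise magnitude, and a seed.
#'
#' @param foci data frame with columns `x`, `y`, `z` (world mm) and
#'   `radius_mm` (> 0); one row per tumor focus.
#' @param geometry a `volume_geometry` the phantom lives on.
#' @param rater_noise boundary perturbation magnitude in voxels (>= 0).
#' @param n_raters number of simulated raters (default 8).
#' @param seed integer seed.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(foci, geometry, rater_noise = 0, n_raters = 8,
                         seed = 1) {
  stopifnot(is.data.frame(foci),
            all(c("x", "y", "z", "radius_mm") %in% names(foci)))
  if (any(foci$radius_mm <= 0)) stop("focus radii must be positive")
  corners <- voxel_to_world(geometry, rbind(c(0, 0, 0), geometry$shape - 1))
  lo <- pmin(corners[1, ], corners[2, ]); hi <- pmax(corners[1, ], corners[2, ])
  for (i in seq_len(nrow(foci))) {
    c_i <- as.numeric(foci[i, c("x", "y", "z")])
    if (any(c_i - foci$radius_mm[i] < lo) || any(c_i + foci$radius_mm[i] > hi))
      stop("focus ", i, " extends outside the lattice bounds")
  }
  structure(list(foci = foci, geometry = geometry,
                 rater_noise = rater_noise, n_raters = as.integer(n_raters),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a phantom tumor case
#'
#' Voxelizes the spec's spheres into a binary mask (a voxel is foreground
#' iff its centre lies within a sphere), derives a probability map by a
#' soft-edge profile around each sphere boundary (p = 0.5 on the analytic
#' surface, reaching 0/1 at +/- `edge_mm`), and simulates rater variants
#' by perturbing each sphere radius by a seeded uniform offset in
#' [-rater_noise, rater_noise] voxels (so `rater_noise = 0` reproduces
#' the mask exactly). The returned truth table is computed from the
#' actual voxelized lattice, not the analytic ideal, so recovery checks
#' can be exact.
#'
#' Foci must voxelize to non-touching components (26-neighbourhood);
#' overlapping or adjacent spheres are rejected.
#'
#' @param spec a `phantom_spec`.
#' @param bundle an `atlas_bundle` on the same geometry.
#' @param edge_mm soft-edge half-width of the probability profile (mm).
#' @return list with `mask` (`binary_mask`), `prob` (`probability_map`),
#'   `raters` (list of `binary_mask`), `truth` (see Details) and `spec`.
#' @export
generate_phantom <- function(spec, bundle, edge_mm = 1.5) {
  geometry <- spec$geometry
  if (!same_geometry(geometry, bundle$geometry))
    stop("spec and bundle geometries differ")
  shp <- geometry$shape
  world <- all_world_coords(geometry)
  nf <- nrow(spec$foci)

  dist_to <- function(i) {
    sqrt((world[, 1] - spec$foci$x[i])^2 + (world[, 2] - spec$foci$y[i])^2 +
         (world[, 3] - spec$foci$z[i])^2)
  }
  focus_vox <- lapply(seq_len(nf), function(i)
    array(dist_to(i) <= spec$foci$radius_mm[i], dim = shp))

  mask_arr <- Reduce(`|`, focus_vox)
  for (i in seq_len(nf))
    if (!any(focus_vox[[i]])) stop("focus ", i, " voxelizes to an empty set")
  counts <- vapply(focus_vox, sum, 1L)
  if (sum(counts) != sum(mask_arr))
    stop("foci overlap after voxelization; move them apart")
  mask <- binary_mask(mask_arr, geometry)
  comps <- connected_components(mask)
  if (length(comps$sizes) != nf)
    stop("foci touch after voxelization; move them apart")

  # Soft-edge probability profile, max over foci.
  prob_arr <- array(0, dim = shp)
  for (i in seq_len(nf)) {
    p <- pmin(1, pmax(0, (spec$foci$radius_mm[i] + edge_mm - dist_to(i)) /
                           (2 * edge_mm)))
    prob_arr <- pmax(prob_arr, array(p, dim = shp))
  }
  prob <- probability_map(prob_arr, geometry)

  raters <- with_seed(spec$seed, {
    lapply(seq_len(spec$n_raters), function(k) {
      if (spec$rater_noise == 0) return(mask)
      offs <- stats::runif(nf, -spec$rater_noise, spec$rater_noise) *
        mean(geometry$spacing)
      arr <- array(FALSE, dim = shp)
      for (i in seq_len(nf))
        arr <- arr | array(dist_to(i) <= spec$foci$radius_mm[i] + offs[i],
                           dim = shp)
      binary_mask(arr, geometry)
    })
  })

  truth <- phantom_truth(spec, bundle, focus_vox, mask, world)
  list(mask = mask, prob = prob, raters = raters, truth = truth, spec = spec)
}

# Ground-truth table computed directly from the voxelized lattice by
# plain counting/summation (no feature-pipeline calls except the shared
# pairwise-distance kernel).
phantom_truth <- function(spec, bundle, focus_vox, mask, world) {
  geometry <- spec$geometry
  vox_ml <- voxel_volume_mm3(geometry) / 1000
  nf <- length(focus_vox)
  counts <- vapply(focus_vox, sum, 1L)
  n <- sum(counts)

  per_focus <- data.frame(
    focus = seq_len(nf),
    analytic_volume_ml = 4 / 3 * pi * spec$foci$radius_mm^3 / 1000,
    voxel_volume_ml = counts * vox_ml)

  n_left <- sum(mask$voxels & (array(world[, 1], dim = geometry$shape) <= 0))
  left_pct <- 100 * n_left / n
  right_pct <- 100 - left_pct

  biggest <- which.max(counts)
  dist_to_biggest <- rep(NA_real_, nf)
  if (nf > 1L) {
    big_coords <- world[as.vector(focus_vox[[biggest]]), , drop = FALSE]
    for (i in setdiff(seq_len(nf), biggest)) {
      ci <- world[as.vector(focus_vox[[i]]), , drop = FALSE]
      dist_to_biggest[i] <- min(cpp_min_dists(ci, big_coords))
    }
  }
  qualifying <- which(!is.na(dist_to_biggest) & dist_to_biggest >= 5.0)
  focus_count <- 1L + length(qualifying)
  satellite_distance <- if (length(qualifying))
    max(dist_to_biggest[qualifying]) else -1.0

  cortical_pct <- unlist(lapply(names(bundle$cortical), function(id) {
    a <- bundle$cortical[[id]]
    stats::setNames(vapply(names(a$names), function(lbl)
      100 * sum(mask$voxels & (a$labels == as.integer(lbl))) / n, numeric(1)),
      sprintf("cortical.%s.%s", id, unname(a$names)))
  }))

  sub <- bundle$subcortical
  sub_pct <- vapply(names(sub$structures), function(s)
    100 * sum(mask$voxels & (sub$structures[[s]] >= sub$threshold)) / n,
    numeric(1))

  hm <- if (left_pct >= right_pct) bundle$heatmap$left_map
        else bundle$heatmap$right_map
  resectable_ml <- sum(hm[mask$voxels]) * vox_ml
  tumor_ml <- n * vox_ml

  list(per_focus = per_focus,
       total_volume_ml = tumor_ml,
       left_pct = left_pct, right_pct = right_pct,
       midline_crossing = n_left >= 1L && (n - n_left) >= 1L,
       biggest_focus = biggest,
       dist_to_biggest_mm = dist_to_biggest,
       multifocal = focus_count > 1L,
       focus_count = focus_count,
       satellite_distance_mm = satellite_distance,
       cortical_pct = cortical_pct,
       subcortical_pct = sub_pct,
       expected_resectable_ml = resectable_ml,
       resectability_index = resectable_ml / tumor_ml)
}

#' Write a ready-to-use synthetic case directory
#'
#' Writes the atlas bundle, the phantom mask, probability map and rater
#' masks as NIfTI, and the truth table as CSV, so the full pipeline can
#' be exercised from disk.
#'
#' @param phantom result of [generate_phantom()].
#' @param bundle the `atlas_bundle` used.
#' @param directory output directory.
#' @return `directory`, invisibly.
#' @export
write_case <- function(phantom, bundle, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  write_bundle(bundle, file.path(directory, "atlas"))
  write_volume(phantom$mask, file.path(directory, "tumor_mask.nii.gz"))
  write_volume(phantom$prob, file.path(directory, "tumor_prob.nii.gz"))
  for (k in seq_along(phantom$raters))
    write_volume(phantom$raters[[k]],
                 file.path(directory, sprintf("rater_%02d.nii.gz", k)))
  tr <- phantom$truth
  scalars <- data.frame(
    quantity = c("total_volume_ml", "left_pct", "right_pct",
                 "midline_crossing", "multifocal", "focus_count",
                 "satellite_distance_mm", "resectability_index"),
    value = c(tr$total_volume_ml, tr$left_pct, tr$right_pct,
              as.numeric(tr$midline_crossing), as.numeric(tr$multifocal),
              tr$focus_count, tr$satellite_distance_mm,
              tr$resectability_index))
  utils::write.csv(scalars, file.path(directory, "truth.csv"),
                   row.names = FALSE)
  invisible(directory)
}
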