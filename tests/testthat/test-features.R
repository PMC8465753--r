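test_that("refinement drops sub-0.1 mL objects with a strict threshold", {
  g <- iso_geom(c(30, 30, 30))   # 1 mm isotropic: 1 voxel = 0.001 mL

  # 50-voxel component (0.05 mL) is removed; closing must not save it
  arr <- array(FALSE, g$shape)
  arr[3:7, 3:7, 3:4] <- TRUE     # 5*5*2 = 50 voxels, compact
  refined <- refine_tumor_mask(binary_mask(arr, g))
  expect_equal(sum(refined$voxels), 0)

  # exactly 0.1 mL (100 voxels) is kept: "smaller than" is strict;
  # a closed box keeps its voxel count through closing
  arr <- array(FALSE, g$shape)
  arr[3:7, 3:7, 3:6] <- TRUE     # 100 voxels, convex
  kept <- refine_tumor_mask(binary_mask(arr, g))
  expect_gte(sum(kept$voxels), 100)

  # big sphere survives, isolated far-away voxel is removed
  sphere <- sphere_mask(g, c(0, 0, 0), 10)
  arr <- sphere$voxels
  arr[29, 29, 29] <- TRUE
  refined <- refine_tumor_mask(binary_mask(arr, g))
  expect_false(refined$voxels[29, 29, 29])
  expect_true(all(refined$voxels[sphere$voxels]))
  # monotonicity: no surviving component smaller than 0.1 mL
  cc <- connected_components(refined)
  expect_true(all(cc$sizes * voxel_volume_mm3(g) / 1000 >= 0.1))
})

test_that("volume is voxel count times voxel volume, in mL", {
  g <- iso_geom(c(10, 10, 10))
  m <- binary_mask(array(TRUE, g$shape), g)
  expect_equal(compute_volume(m), 1.0)
  expect_equal(compute_volume(binary_mask(array(FALSE, g$shape), g)), 0.0)

  ga <- volume_geometry(c(12, 12, 12), c(0.98, 0.99, 1.0))
  set.seed(5)
  arr <- array(FALSE, ga$shape)
  arr[sample(prod(ga$shape), 523)] <- TRUE
  expect_equal(compute_volume(binary_mask(arr, ga)), 523 * 0.9702 / 1000)
})

test_that("laterality percentages and midline crossing follow voxel counts", {
  g <- volume_geometry(c(10, 10, 10))
  hemi <- hemisphere_from_geometry(g)

  left_only <- cube_mask(g, c(1, 1, 1), c(4, 4, 4))
  lat <- compute_laterality(left_only, hemi)
  expect_equal(lat$left_pct, 100)
  expect_equal(lat$right_pct, 0)
  expect_false(lat$midline_crossing)

  # a single voxel on the other side flips the crossing flag
  one_right <- left_only$voxels; one_right[8, 5, 5] <- TRUE
  lat <- compute_laterality(binary_mask(one_right, g), hemi)
  expect_true(lat$midline_crossing)

  # 60 voxels left, 40 right
  arr <- array(FALSE, g$shape)
  arr[1:3, 1:4, 1:5] <- TRUE          # 60 in x=1..3 (left half is x=1..5)
  arr[6:7, 1:4, 1:5] <- TRUE          # 40 in the right half
  lat <- compute_laterality(binary_mask(arr, g), hemi)
  expect_equal(lat$left_pct, 60)
  expect_equal(lat$right_pct, 40)
  expect_true(lat$midline_crossing)
  expect_equal(lat$left_pct + lat$right_pct, 100)

  expect_error(compute_laterality(binary_mask(array(FALSE, g$shape), g), hemi),
               "empty")
})

test_that("multifocality applies the 5 mm satellite rule", {
  g <- iso_geom(c(40, 16, 16))

  single <- cube_mask(g, c(2, 2, 2), c(8, 8, 8))
  mf <- compute_multifocality(single)
  expect_false(mf$multifocal)
  expect_equal(mf$focus_count, 1L)
  expect_equal(mf$satellite_distance_mm, -1.0)

  # satellite 10 mm away (gap of 10 voxels at 1 mm): counted
  two <- single$voxels
  two[18:21, 2:5, 2:5] <- TRUE   # centres 10 mm from the cube's near face
  mf <- compute_multifocality(binary_mask(two, g))
  expect_true(mf$multifocal)
  expect_equal(mf$focus_count, 2L)
  expect_equal(mf$satellite_distance_mm, 10.0)

  # satellite only 3 mm away: not taken into consideration
  close_by <- single$voxels
  close_by[12:14, 2:5, 2:5] <- TRUE
  mf <- compute_multifocality(binary_mask(close_by, g))
  expect_false(mf$multifocal)
  expect_equal(mf$focus_count, 1L)
  expect_equal(mf$satellite_distance_mm, -1.0)

  # biggest focus is chosen by volume; auxiliary diameters are reported
  expect_true(mf$foci$biggest[which.max(mf$foci$volume_ml)])
  expect_equal(mf$foci$diameter_mm,
               2 * (3 * mf$foci$volume_ml * 1000 / (4 * pi))^(1 / 3))
})

test_that("resectability integrates the dominant-hemisphere heat map", {
  g <- volume_geometry(c(10, 10, 10))
  hemi <- hemisphere_from_geometry(g)
  tumor <- cube_mask(g, c(1, 1, 1), c(3, 3, 3))   # fully left
  lat <- compute_laterality(tumor, hemi)

  zeros <- resection_heatmap(array(0, g$shape), array(0, g$shape), g)
  res <- compute_resectability(tumor, zeros, lat)
  expect_equal(res$resectability_index, 0.0)
  expect_equal(res$expected_residual_ml, compute_volume(tumor))

  ones <- resection_heatmap(array(1, g$shape), array(1, g$shape), g)
  res <- compute_resectability(tumor, ones, lat)
  expect_equal(res$resectability_index, 1.0)
  expect_equal(res$expected_residual_ml, 0.0)

  # 3 voxels with probabilities 0.2 / 0.5 / 0.8 -> index 0.5
  small <- mask_from_indices(g, rbind(c(1, 1, 1), c(2, 1, 1), c(3, 1, 1)))
  hm <- array(0, g$shape)
  hm[1, 1, 1] <- 0.2; hm[2, 1, 1] <- 0.5; hm[3, 1, 1] <- 0.8
  res <- compute_resectability(small, resection_heatmap(hm, array(0, g$shape), g),
                               compute_laterality(small, hemi))
  expect_equal(res$expected_residual_ml + 0.0015, compute_volume(small))
  expect_equal(res$resectability_index, 0.5)

  # the dominant hemisphere selects the map: mostly-right tumor uses right
  right_tumor <- cube_mask(g, c(7, 1, 1), c(9, 3, 3))
  latr <- compute_laterality(right_tumor, hemi)
  res <- compute_resectability(right_tumor,
                               resection_heatmap(array(0, g$shape),
                                                 array(1, g$shape), g), latr)
  expect_equal(res$resectability_index, 1.0)
})

test_that("cortical profile reports per-structure overlap percentages", {
  bundle <- test_bundle()
  g <- bundle$geometry
  labels7 <- bundle$cortical[["Schaefer7"]]$labels

  # tumor entirely inside one structure
  inside <- binary_mask(labels7 == 3L, g)
  prof <- cortical_profile(inside, bundle$cortical)
  s7 <- prof[grep("^cortical\\.Schaefer7\\.", names(prof))]
  name3 <- sprintf("cortical.Schaefer7.%s",
                   bundle$cortical[["Schaefer7"]]$names[["3"]])
  expect_equal(unname(s7[name3]), 100)
  expect_equal(sum(s7), 100)

  # tumor wholly outside labelled voxels: all zero for that atlas
  corner <- cube_mask(g, c(1, 1, 1), c(2, 2, 2))   # inside the margin
  prof <- cortical_profile(corner, bundle$cortical)
  expect_true(all(prof == 0))

  # half in A, half in B for a constructed two-label split
  half <- binary_mask(labels7 %in% c(1L, 2L), g)
  prof <- cortical_profile(half, bundle$cortical)
  n1 <- sum(labels7 == 1L); n2 <- sum(labels7 == 2L)
  expect_equal(unname(prof[sprintf("cortical.Schaefer7.%s",
                                   bundle$cortical[["Schaefer7"]]$names[["1"]])]),
               100 * n1 / (n1 + n2))
  # within each atlas overlaps sum to <= 100
  for (id in names(bundle$cortical)) {
    s <- prof[grep(sprintf("^cortical\\.%s\\.", id), names(prof))]
    expect_lte(sum(s), 100 + 1e-9)
  }
})

test_that("subcortical profile distances follow the overlap rule", {
  g <- iso_geom(c(24, 12, 12))
  nm <- c(sprintf("tract_%02d_left", 1:28), sprintf("tract_%02d_right", 1:28),
          sprintf("commissural_%02d", 1:12))
  zero <- array(0, g$shape)
  structures <- stats::setNames(rep(list(zero), 68), nm)
  # structure 1: a cube the tumor overlaps; structure 2: a distant cube;
  # structure 3: everywhere sub-threshold
  s1 <- zero; s1[2:4, 2:4, 2:4] <- 1
  s2 <- zero; s2[18:20, 2:4, 2:4] <- 1
  s3 <- zero + 0.49
  structures[[1]] <- s1; structures[[2]] <- s2; structures[[3]] <- s3
  atlas <- probabilistic_atlas(structures, g)

  tumor <- cube_mask(g, c(4, 2, 2), c(6, 4, 4))   # shares voxels with s1
  prof <- subcortical_profile(tumor, atlas)
  expect_gt(prof$overlap_pct[[nm[1]]], 0)
  expect_equal(prof$distance_mm[[nm[1]]], 0.0)
  expect_equal(prof$overlap_pct[[nm[3]]], 0)
  expect_equal(prof$distance_mm[[nm[3]]], -1.0)   # empty after thresholding

  # distance to the distant structure: directed 95th percentile from the
  # tumor boundary to the structure mask, against the brute-force oracle
  sa <- oracle_world_coords(oracle_surface(tumor$voxels), g)
  sb <- oracle_world_coords(s2 >= 0.5, g)
  d <- oracle_dist_matrix(sa, sb)
  expected <- as.numeric(stats::quantile(apply(d, 1, min), 0.95))
  expect_equal(prof$distance_mm[[nm[2]]], expected)
  expect_gt(prof$distance_mm[[nm[2]]], 0)
})

test_that("assembled record carries 233 features with stable names", {
  bundle <- test_bundle()
  g <- bundle$geometry
  tumor <- sphere_mask(g, c(-5, 0, 0), 6)
  rec <- tumor_features(tumor, bundle, patient_id = "case-1")
  v <- feature_vector(rec)

  expect_length(v, 233)
  expect_equal(sum(startsWith(names(v), "cortical.")), 87)
  expect_equal(sum(startsWith(names(v), "subcortical_overlap.")), 68)
  expect_equal(sum(startsWith(names(v), "subcortical_distance.")), 68)
  expect_false(anyDuplicated(names(v)) > 0)
  expect_identical(names(v), feature_names(bundle))

  # identical patient and reference masks give equal volume features
  expect_equal(v[["volume.patient_space_ml"]], v[["volume.mni_space_ml"]])
  expect_equal(v[["laterality.left_pct"]] + v[["laterality.right_pct"]], 100)
  expect_gte(v[["resectability.resectability_index"]], 0)
  expect_lte(v[["resectability.resectability_index"]], 1)
  expect_true(all(v[startsWith(names(v), "cortical.")] >= 0))
  expect_true(all(v[startsWith(names(v), "cortical.")] <= 100))

  # conservation: residual + resectable = tumor volume
  res <- compute_resectability(tumor, bundle$heatmap,
                               compute_laterality(tumor, bundle$hemisphere))
  expect_equal(res$expected_residual_ml + res$expected_resectable_ml,
               compute_volume(tumor), tolerance = 1e-9)

  # empty mask: explicit no-tumor record, not silent zeros
  empty <- binary_mask(array(FALSE, g$shape), g)
  rec0 <- tumor_features(empty, bundle)
  expect_true(is_empty_record(rec0))
  expect_error(feature_vector(rec0), "no tumor")
})
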