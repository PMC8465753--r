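test_that("geometry construction validates shape, spacing and affine", {
  g <- volume_geometry(c(10, 12, 14), c(0.98, 0.99, 1.0))
  expect_s3_class(g, "volume_geometry")
  expect_equal(voxel_volume_mm3(g), 0.98 * 0.99 * 1.0)
  expect_error(volume_geometry(c(10, 12), c(1, 1, 1)), "shape")
  expect_error(volume_geometry(c(10, 12, 14), c(1, -1, 1)), "spacing")
  bad_affine <- diag(4); bad_affine[1, 1] <- 0
  expect_error(volume_geometry(c(10, 12, 14), c(1, 1, 1), bad_affine),
               "invertible")
  # spacing must agree with affine column norms within 1e-3 mm
  aff <- diag(4); diag(aff)[1:3] <- c(1.01, 1, 1)
  expect_error(volume_geometry(c(10, 12, 14), c(1, 1, 1), aff), "inconsistent")
})

test_that("default affine centres the lattice so world x=0 is the midline", {
  g <- volume_geometry(c(48, 56, 48))
  w <- voxel_to_world(g, rbind(c(0, 0, 0), c(47, 55, 47)))
  expect_equal(w[1, ], -w[2, ])
  expect_equal(world_to_voxel(g, w[2, , drop = FALSE])[1, ], c(47, 55, 47))
})

test_that("NIfTI round trip preserves voxels, spacing and affine", {
  g <- volume_geometry(c(10, 10, 10), c(0.98, 0.99, 1.0))
  path <- withr::local_tempfile(fileext = ".nii.gz")

  zero <- binary_mask(array(FALSE, g$shape), g)
  write_volume(zero, path)
  back <- read_volume(path)
  expect_s3_class(back, "binary_mask")
  expect_identical(back$voxels, zero$voxels)
  expect_equal(back$geometry$spacing, g$spacing, tolerance = 1e-5)

  arr <- array(FALSE, g$shape); arr[2:4, 3:5, 4:6] <- TRUE
  m <- binary_mask(arr, g)
  write_volume(m, path)
  back <- read_volume(path)
  expect_s3_class(back, "binary_mask")
  expect_identical(back$voxels, m$voxels)
  expect_lt(max(abs(back$geometry$affine - g$affine)), 1e-5)

  vals <- array(0, g$shape); vals[1:5, , ] <- 0.3; vals[6, 1, 1] <- 0.9
  p <- probability_map(vals, g)
  write_volume(p, path)
  back <- read_volume(path)
  expect_s3_class(back, "probability_map")
  expect_equal(max(back$values), 0.9, tolerance = 1e-6)
  expect_equal(sort(unique(as.vector(back$values))), c(0, 0.3, 0.9),
               tolerance = 1e-6)
})

test_that("volume reader rejects the invalid and classifies by content", {
  expect_error(read_volume(file.path(tempdir(), "nope.nii.gz")), "cannot read")
  g <- iso_geom(c(6, 6, 6))
  # a float file whose values exceed [0,1] must be rejected
  path <- withr::local_tempfile(fileext = ".nii.gz")
  gliomask:::write_nifti_array(array(seq(0, 2, length.out = 216), g$shape),
                               g, path, "float")
  expect_error(read_volume(path), "outside")
  # probability construction rejects out-of-range and non-finite values
  expect_error(probability_map(array(2, g$shape), g), "\\[0, 1\\]")
  expect_error(probability_map(array(NaN, g$shape), g), "finite")
})

test_that("connected components match the neighbourhood definition", {
  g <- iso_geom(c(20, 10, 10))
  empty <- binary_mask(array(FALSE, g$shape), g)
  expect_length(connected_components(empty)$sizes, 0)

  two <- cube_mask(g, c(1, 1, 1), c(3, 3, 3))
  two$voxels[9:11, 1:3, 1:3] <- TRUE   # 5-voxel gap from the first cube
  two <- binary_mask(two$voxels, g)
  cc <- connected_components(two, 26)
  expect_equal(sort(cc$sizes), c(27, 27))
  expect_equal(sum(cc$sizes), sum(two$voxels))

  # corner-touching cubes: one object under 26, two under 6
  corner <- cube_mask(g, c(1, 1, 1), c(2, 2, 2))
  corner$voxels[3:4, 3:4, 3:4] <- TRUE
  corner <- binary_mask(corner$voxels, g)
  expect_length(connected_components(corner, 26)$sizes, 1)
  expect_length(connected_components(corner, 6)$sizes, 2)
  expect_error(connected_components(corner, 10), "connectivity")
})

test_that("binary closing is extensive, idempotent on closed sets, and fills slits", {
  g <- iso_geom(c(20, 20, 20))
  empty <- binary_mask(array(FALSE, g$shape), g)
  expect_identical(binary_closing(empty, 2, 1)$voxels, empty$voxels)

  sphere <- sphere_mask(g, c(0, 0, 0), 6)
  closed <- binary_closing(sphere, 2, 1)
  # extensivity and idempotence on an already-closed convex solid
  expect_true(all(closed$voxels >= sphere$voxels))
  twice <- binary_closing(closed, 2, 1)
  expect_identical(twice$voxels, closed$voxels)

  # internal 1-voxel slit: result equals the reference morphology oracle,
  # and the deep part of the slit is filled
  slit <- sphere$voxels
  slit[, 10, ] <- FALSE
  slit_mask <- binary_mask(slit, g)
  healed <- binary_closing(slit_mask, 2, 1)
  expect_identical(healed$voxels, oracle_closing(slit, 2, 1))
  expect_gt(sum(healed$voxels & !slit), 0)
  expect_true(healed$voxels[10, 10, 10])

  # border-touching objects are never eaten (zero-padded closing)
  corner <- cube_mask(g, c(1, 1, 1), c(3, 3, 3))
  expect_true(all(binary_closing(corner, 2, 2)$voxels[corner$voxels]))
})

test_that("dice follows its definition and conventions", {
  g <- iso_geom(c(10, 10, 10))
  a <- cube_mask(g, c(1, 1, 1), c(5, 4, 5))   # 100 voxels
  expect_equal(dice(a, a), 1.0)
  empty <- binary_mask(array(FALSE, g$shape), g)
  expect_equal(dice(empty, empty), 1.0)
  expect_equal(dice(a, empty), 0.0)
  b <- cube_mask(g, c(6, 6, 6), c(10, 9, 10))
  expect_equal(dice(a, b), 0.0)
  # |a|=100, |b|=100, intersection 50
  c_ <- cube_mask(g, c(1, 3, 1), c(5, 6, 5))
  expect_equal(sum(c_$voxels), 100)
  expect_equal(sum(a$voxels & c_$voxels), 50)
  expect_equal(dice(a, c_), 0.5)
  g2 <- iso_geom(c(9, 9, 9))
  expect_error(dice(a, binary_mask(array(FALSE, g2$shape), g2)), "geometry")
})

test_that("hd95 and min_surface_distance work in world millimetres", {
  g <- iso_geom(c(15, 15, 15))
  a <- mask_from_indices(g, cbind(3, 8, 8))
  b <- mask_from_indices(g, cbind(13, 8, 8))
  expect_equal(hd95(a, b), 10.0)
  expect_equal(hd95(a, a), 0.0)
  expect_true(is.na(hd95(a, binary_mask(array(FALSE, g$shape), g))))

  c_ <- mask_from_indices(g, cbind(6, 8, 8))
  expect_equal(min_surface_distance(a, c_), 3.0)
  over <- mask_from_indices(g, rbind(c(3, 8, 8), c(4, 8, 8)))
  expect_equal(min_surface_distance(a, over), 0.0)
  expect_error(min_surface_distance(a, binary_mask(array(FALSE, g$shape), g)),
               "non-empty")

  # anisotropic spacing: offset by one voxel on each axis
  ga <- volume_geometry(c(10, 10, 10), c(0.98, 0.99, 1.0))
  p <- mask_from_indices(ga, cbind(4, 4, 4))
  q <- mask_from_indices(ga, cbind(5, 5, 5))
  expect_equal(min_surface_distance(p, q), sqrt(0.98^2 + 0.99^2 + 1.0^2))
})

test_that("nearest-neighbour resampling is exact for identity and integer shifts", {
  g <- iso_geom(c(12, 12, 12))
  m <- sphere_mask(g, c(0, 0, 0), 4)
  expect_identical(resample_to_geometry(m, g)$voxels, m$voxels)

  # integer-voxel translation: shifted mask exactly
  aff <- g$affine
  aff[1, 4] <- aff[1, 4] + 3   # target origin shifted +3 mm in x
  g_shift <- volume_geometry(g$shape, g$spacing, aff)
  shifted <- resample_to_geometry(m, g_shift)
  expect_identical(shifted$voxels[1:9, , ], m$voxels[4:12, , ])

  # double spacing then back: aliasing stays within 2 voxels of the
  # boundary, so the deep interior survives and nothing appears 2 voxels
  # outside the original
  g_coarse <- volume_geometry(c(6, 6, 6), c(2, 2, 2))
  back <- resample_to_geometry(resample_to_geometry(m, g_coarse), g)
  box1 <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  chebyshev_erode <- function(arr, n) {
    v <- as.vector(arr)
    for (i in seq_len(n)) v <- gliomask:::cpp_erode(v, dim(arr), box1)
    array(v, dim(arr))
  }
  chebyshev_dilate <- function(arr, n) {
    v <- as.vector(arr)
    for (i in seq_len(n)) v <- gliomask:::cpp_dilate(v, dim(arr), box1)
    array(v, dim(arr))
  }
  deep <- chebyshev_erode(m$voxels, 2)
  grown <- chebyshev_dilate(m$voxels, 2)
  expect_true(all(back$voxels[deep]))
  expect_false(any(back$voxels[!grown]))
})

test_that("metric operators are symmetric and non-negative on random masks", {
  set.seed(11)
  g <- iso_geom(c(10, 10, 10))
  for (i in 1:10) {
    a_arr <- random_lattice(g$shape)
    b_arr <- random_lattice(g$shape)
    a <- binary_mask(a_arr, g); b <- binary_mask(b_arr, g)
    expect_equal(dice(a, b), dice(b, a))
    if (any(a_arr) && any(b_arr)) {
      h1 <- hd95(a, b); h2 <- hd95(b, a)
      expect_equal(h1, h2)
      expect_gte(h1, 0)
      sa <- oracle_world_coords(oracle_surface(a_arr), g)
      sb <- oracle_world_coords(oracle_surface(b_arr), g)
      expect_lte(h1, max(oracle_dist_matrix(sa, sb)))
    }
  }
})
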