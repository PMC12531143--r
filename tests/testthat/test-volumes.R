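test_that("NIfTI round trip preserves data, affine and TR", {
  tmpl <- grid_template(c(5, 5, 5))
  v <- vol3d(array(rnorm(125), c(5, 5, 5)), tmpl$affine)
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(v, f)
  back <- read_volume(f)
  expect_equal(back$data, v$data, tolerance = 1e-6)
  expect_equal(back$affine, v$affine, tolerance = 1e-6)

  v4 <- vol4d(array(rnorm(5 * 5 * 5 * 120), c(5, 5, 5, 120)), tmpl$affine,
              tr_seconds = 0.72)
  f4 <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(v4, f4)
  back4 <- read_volume(f4)
  expect_s3_class(back4, "vol4d")
  expect_equal(dim(back4$data)[4], 120)
  expect_equal(back4$tr_seconds, 0.72, tolerance = 1e-6)
})

test_that("unreadable input raises I/O errors", {
  expect_error(read_volume(tempfile()), "not found")
  bad <- withr::local_tempfile(fileext = ".nii")
  writeBin(as.raw(1:40), bad)
  expect_error(suppressWarnings(read_volume(bad)), "NIfTI")
})

test_that("mm/voxel conversion matches hand-solved affines and inverts", {
  ident <- diag(4)
  expect_equal(drop(mm_to_voxel(ident, c(2, 3, 4))), c(2, 3, 4))
  aff <- rbind(cbind(diag(3) * 3, c(-9, -9, -9)), c(0, 0, 0, 1))
  expect_equal(drop(mm_to_voxel(aff, c(0, 0, 0))), c(3, 3, 3))
  vox <- matrix(runif(30, 0, 10), ncol = 3)
  expect_equal(mm_to_voxel(aff, voxel_to_mm(aff, vox)), vox,
               tolerance = 1e-10)
  expect_error(mm_to_voxel(matrix(0, 4, 4), c(0, 0, 0)), "invertible")
})

test_that("sphere seeds match hand-derived voxel counts", {
  tmpl <- grid_template(c(11, 11, 11), 3)
  # 4-mm ball around a voxel center on a 3-mm grid: center + 6 face
  # neighbors (3 mm); diagonal neighbors at 3*sqrt(2) ~ 4.24 mm excluded
  expect_equal(sum(make_sphere_seed(c(0, 0, 0), 4, tmpl)$data), 7)
  expect_equal(sum(make_sphere_seed(c(0, 0, 0), 1, tmpl)$data), 1)
  one <- make_sphere_seed(c(0, 0, 0), 4, tmpl)
  two <- make_sphere_seed(rbind(c(0, 0, 0), c(0, 0, 0)), 4, tmpl)
  expect_equal(two$data, one$data)
  expect_error(make_sphere_seed(c(500, 500, 500), 4, tmpl), "empty seed")
})

test_that("sphere voxel count grows with radius and matches the oracle", {
  tmpl <- grid_template(c(13, 13, 13), 3)
  counts <- vapply(c(1, 4, 7), function(r)
    sum(make_sphere_seed(c(0, -3, 0), r, tmpl)$data), numeric(1))
  expect_equal(counts, c(1, 7, 57))   # hand-enumerated 3-mm lattice balls
  expect_true(all(diff(counts) > 0))

  set.seed(7)
  for (i in 1:12) {
    dims <- sample(6:12, 3, replace = TRUE)
    tmpl <- grid_template(dims, spacing = sample(c(2, 3), 1))
    coords <- matrix(runif(6, -8, 8), ncol = 3)
    r <- runif(1, 2, 8)
    oracle <- sphere_oracle(coords, r, tmpl)
    if (sum(oracle) == 0) {
      expect_error(make_sphere_seed(coords, r, tmpl), "empty seed")
    } else {
      expect_equal(make_sphere_seed(coords, r, tmpl)$data, oracle)
    }
  }
})

test_that("Gaussian smoothing is identity at fwhm 0, flat on constants, and mass-conserving", {
  tmpl <- grid_template(c(15, 15, 15), 3)
  v <- vol3d(array(rnorm(15^3), c(15, 15, 15)), tmpl$affine)
  expect_identical(smooth_gaussian(v, 0), v)

  const <- vol3d(array(2.5, c(15, 15, 15)), tmpl$affine)
  sm <- smooth_gaussian(const, 6)
  expect_equal(sm$data, const$data, tolerance = 1e-10)

  delta <- array(0, c(15, 15, 15)); delta[8, 8, 8] <- 1
  out <- smooth_gaussian(vol3d(delta, tmpl$affine), 6)
  expect_equal(sum(out$data), 1, tolerance = 1e-8)
  expect_error(smooth_gaussian(v, -1), "nonnegative")
})

test_that("smoothing obeys the Gaussian semigroup property", {
  tmpl <- grid_template(c(17, 17, 17), 3)
  delta <- array(0, c(17, 17, 17)); delta[9, 9, 9] <- 1
  v <- vol3d(delta, tmpl$affine)
  twice <- smooth_gaussian(smooth_gaussian(v, 4), 5)
  once <- smooth_gaussian(v, sqrt(4^2 + 5^2))
  expect_equal(twice$data, once$data, tolerance = 2e-3)
})

test_that("coordinate filtering partitions the input by mask membership", {
  tmpl <- grid_template(c(9, 9, 9), 3)
  m <- array(0, c(9, 9, 9)); m[1:4, , ] <- 1   # x in [-12, -3] mm retained
  mask <- brain_mask(m, tmpl$affine)
  coords <- rbind(c(-12, 0, 0), c(12, 0, 0), c(-6, 3, -3), c(0, 0, 0))
  part <- filter_coords_in_mask(coords, mask)
  expect_equal(part$retained_idx, c(1L, 3L))
  expect_equal(nrow(part$retained) + nrow(part$dropped), nrow(coords))
  expect_equal(part$retained, coords[c(1, 3), ])

  all_in <- filter_coords_in_mask(coords[c(1, 3), ], mask)
  expect_equal(nrow(all_in$dropped), 0)
  all_out <- filter_coords_in_mask(coords[c(2, 4), ], mask)
  expect_equal(nrow(all_out$retained), 0)
  # out-of-grid coordinates are dropped, not an error
  far <- filter_coords_in_mask(c(1e4, 0, 0), mask)
  expect_equal(nrow(far$retained), 0)
})

test_that("dice handles identical, disjoint and empty masks", {
  tmpl <- grid_template(c(6, 6, 6), 3)
  a <- array(0, c(6, 6, 6)); a[1:3, , ] <- 1
  b <- array(0, c(6, 6, 6)); b[4:6, , ] <- 1
  ma <- brain_mask(a, tmpl$affine); mb <- brain_mask(b, tmpl$affine)
  expect_equal(dice(ma, ma), 1)
  expect_equal(dice(ma, mb), 0)
  z <- brain_mask(array(0, c(6, 6, 6)), tmpl$affine)
  expect_equal(dice(z, z), 1)
  expect_error(dice(ma, brain_mask(array(0, c(5, 6, 6)),
                                   grid_template(c(5, 6, 6))$affine)),
               "geometry mismatch")
})
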