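test_that("standardization lands any input on the target grid", {
  g <- grid_spec() # 96 x 96 x 37 @ 3 mm
  for (src in list(list(d = c(64, 64, 32), sp = c(4, 4, 3)),
                   list(d = c(80, 80, 32), sp = c(3.4, 3.4, 3.4)),
                   list(d = c(50, 70, 20), sp = c(3, 3, 5)))) {
    v <- volume3d(array(runif(prod(src$d), 0, 1000), src$d), src$sp)
    out <- standardize_volume(v, g)
    expect_equal(dim(out$volume$data), c(96L, 96L, 37L))
    expect_equal(out$volume$spacing, c(3, 3, 3))
    expect_false(any(out$record$crop_flags))
  }
})

test_that("standardizing an already-standard volume leaves data unchanged", {
  g <- grid_spec()
  v <- volume3d(array(runif(96 * 96 * 37), c(96, 96, 37)), c(3, 3, 3))
  out <- standardize_volume(v, g, normalize = FALSE)
  expect_equal(out$volume$data, v$data, tolerance = 1e-12)
  zero <- standardize_volume(volume3d(array(0, c(40, 40, 20)), c(4, 4, 4)), g,
                             normalize = FALSE)
  expect_true(all(zero$volume$data == 0))
})

test_that("oversized inputs are centre-cropped with a warning and crop flags", {
  g <- grid_spec(c(16, 16, 8), 4) # 64 x 64 x 32 mm extent
  v <- volume3d(array(runif(40 * 40 * 10), c(40, 40, 10)), c(2, 2, 2)) # 80 mm in-plane
  expect_warning(out <- standardize_volume(v, g), "crop")
  expect_equal(out$record$crop_flags, c(TRUE, TRUE, FALSE))
})

test_that("robust intensity normalization maps to [0,1], monotonically", {
  ramp <- volume3d(array(seq(0, 1000, length.out = 20^3), c(20, 20, 20)), c(3, 3, 3))
  nz <- normalize_intensity(ramp)
  expect_equal(range(nz$volume$data), c(0, 1))
  # oracle: the percentile formula applied directly
  q <- quantile(ramp$data, c(0.01, 0.99), names = FALSE)
  manual <- pmin(1, pmax(0, (ramp$data - q[1]) / (q[2] - q[1])))
  expect_equal(as.vector(nz$volume$data), as.vector(manual), tolerance = 1e-12)
  # weak monotonicity
  x <- as.vector(ramp$data); y <- as.vector(nz$volume$data)
  o <- order(x)
  expect_true(all(diff(y[o]) >= 0))
  # constant image: all zeros, no division blow-up
  const <- normalize_intensity(volume3d(array(7, c(5, 5, 5)), c(1, 1, 1)))
  expect_true(all(const$volume$data == 0))
})

test_that("mask transport to standard space and back loses only boundary voxels", {
  set.seed(42)
  # native coarser than the standard grid, as in deployment
  g <- grid_spec(c(34, 34, 34), 3) # 102 mm extent
  for (i in 1:6) {
    m <- random_ellipsoid(c(24, 24, 24), c(4, 4, 4), min_vox = 500)
    std <- standardize_mask(m, g)
    rec <- standardize_volume(volume3d(array(0, dim(m$data)), m$spacing), g,
                              normalize = FALSE)$record
    back <- invert_standardization(std, rec)
    expect_true(all(back$data %in% c(0, 1)))
    expect_gte(dice_coefficient(back$data, m$data), 0.95)
  }
})

test_that("empty and full masks transport to empty and full", {
  g <- grid_spec(c(20, 20, 20), 5)
  src_dim <- c(24, 24, 24); sp <- c(4, 4, 4)
  rec <- standardize_volume(volume3d(array(0, src_dim), sp), g, normalize = FALSE)$record
  empty <- standardize_mask(volume3d(array(0, src_dim), sp), g)
  expect_true(all(invert_standardization(empty, rec)$data == 0))
  full <- volume3d(array(1, g$target_shape), g$target_spacing)
  expect_true(all(invert_standardization(full, rec)$data == 1))
})

test_that("record/shape mismatch is rejected", {
  g <- grid_spec(c(20, 20, 20), 5)
  rec <- standardize_volume(volume3d(array(0, c(24, 24, 24)), c(4, 4, 4)), g)$record
  wrong <- volume3d(array(0, c(10, 10, 10)), c(5, 5, 5))
  expect_error(invert_standardization(wrong, rec), "shape")
})
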