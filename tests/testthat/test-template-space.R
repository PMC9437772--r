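test_that("a template registers to itself as the identity", {
  ph <- generate_phantom(phantom_spec(n_frames = 1, seed = 71))
  xfm <- register_affine(ph$template, ph$template)
  expect_lt(max(abs(xfm$matrix - diag(4))), 1e-3)
})

test_that("a known isotropic scaling is recovered within 2 percent", {
  ph <- generate_phantom(phantom_spec(n_frames = 1, seed = 44, noise_sd = 10))
  tpl <- ph$template
  S <- diag(c(1.1, 1.1, 1.1, 1)) # moving samples the template at 1.1x coordinates
  mov <- tpl
  mov$data <- resample_volume(tpl, dim(tpl$data), tpl$affine, world = S)
  xfm <- register_affine(mov, tpl)
  sv <- svd(xfm$matrix[1:3, 1:3])$d
  expect_true(all(abs(sv - 1 / 1.1) < 0.02 / 1.1))
})

test_that("composing a known rigid offset with the fit recovers the combined map", {
  ph <- generate_phantom(phantom_spec(n_frames = 1, seed = 72, noise_sd = 5))
  tpl <- ph$template
  M <- rigid_matrix(rigid_transform(3, -2, 1, 0.03, 0, -0.02),
                    fetalmask:::world_center(tpl))
  mov <- tpl
  mov$data <- resample_volume(tpl, dim(tpl$data), tpl$affine, world = M)
  # the fitted map resamples mov onto the template grid, so it must
  # recover the inverse of the offset used to build mov
  xfm <- register_affine(mov, tpl)
  # entries are dominated by the translation column (mm); sub-half-mm
  # recovery of a composed 3 mm / ~2 degree offset
  expect_lt(max(abs(xfm$matrix - solve(M))), 0.5)
})

test_that("warping preserves frame count, identity is exact, masks stay binary", {
  ph <- generate_phantom(phantom_spec(n_frames = 3, seed = 73))
  s <- ph$series
  out <- warp_series(s, diag(4), get_frame(s, 1))
  expect_equal(n_frames(out), 3)
  expect_equal(out$data, s$data, tolerance = 1e-12) # identity on the same grid
  mask_series <- merge_volumes(ph$truth_masks)
  wm <- warp_series(mask_series, diag(4), ph$truth_masks[[1]], method = "nearest")
  expect_true(all(wm$data %in% c(0, 1)))
})

test_that("smoothing conserves interior mass and fwhm 0 is the identity", {
  d <- c(21, 21, 15)
  imp <- array(0, d); imp[11, 11, 8] <- 5
  s <- time_series4d(array(imp, c(d, 1)), spacing = c(3, 3, 3))
  out <- smooth_series(s, fwhm_mm = 6)
  expect_equal(sum(out$data), 5, tolerance = 1e-6) # kernel mass conserved
  expect_identical(smooth_series(s, 0)$data, s$data)
  expect_error(smooth_series(s, -1), "non-negative")
})

test_that("smoothing twice with f equals once with f*sqrt(2) (Gaussian semigroup)", {
  set.seed(74)
  d <- c(24, 24, 16)
  arr <- array(rnorm(prod(d)), c(d, 1))
  s <- time_series4d(arr, spacing = c(3, 3, 3))
  f <- 8
  twice <- smooth_series(smooth_series(s, f), f)
  once <- smooth_series(s, f * sqrt(2))
  interior <- list(5:20, 5:20, 5:12)
  a <- twice$data[interior[[1]], interior[[2]], interior[[3]], 1]
  b <- once$data[interior[[1]], interior[[2]], interior[[3]], 1]
  expect_lt(sqrt(mean((a - b)^2)) / sd(b), 1e-2)
})

test_that("transforms round-trip through the 4x4 text format", {
  M <- rigid_matrix(rigid_transform(1.5, -2, 3, 0.1, 0.05, -0.2), c(1, 2, 3))
  f <- withr::local_tempfile(fileext = ".mat")
  write_transform(M, f)
  expect_equal(read_transform(f), M, tolerance = 1e-10)
})
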