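test_that("a phantom is bit-identical for the same seed", {
  a <- generate_phantom(phantom_spec(n_frames = 3, seed = 81, ghost_fraction = 0.3))
  b <- generate_phantom(phantom_spec(n_frames = 3, seed = 81, ghost_fraction = 0.3))
  expect_identical(a$series$data, b$series$data)
  expect_identical(a$truth_motion, b$truth_motion)
  expect_identical(lapply(a$truth_masks, `[[`, "data"),
                   lapply(b$truth_masks, `[[`, "data"))
  c3 <- generate_phantom(phantom_spec(n_frames = 3, seed = 82))
  expect_false(identical(a$series$data, c3$series$data))
})

test_that("ground-truth mask volume matches the analytic ellipsoid within 5 percent", {
  for (seed in c(83, 84, 85)) {
    spec <- phantom_spec(n_frames = 1, seed = seed,
                         pseudo_age_weeks = runif(1, 24, 39))
    ph <- generate_phantom(spec)
    analytic <- 4 / 3 * pi * prod(spec$brain_axes_mm) / prod(spec$spacing)
    expect_lt(abs(sum(ph$truth_masks[[1]]$data) - analytic) / analytic, 0.05)
  }
})

test_that("a motionless, noiseless, ghost-free phantom has identical frames", {
  spec <- phantom_spec(n_frames = 3, seed = 86, noise_sd = 0, ghost_fraction = 0,
                       jump_trans_mm = 0, jump_rot_deg = 0, jitter_sd_mm = 0,
                       quiescent_frames = c(10, 10))
  ph <- generate_phantom(spec)
  expect_identical(ph$series$data[, , , 2], ph$series$data[, , , 1])
  expect_identical(ph$series$data[, , , 3], ph$series$data[, , , 1])
  expect_identical(ph$truth_masks[[2]]$data, ph$truth_masks[[1]]$data)
})

test_that("the maternal compartment is filled, structured, and rim-bright", {
  ph <- generate_phantom(phantom_spec(n_frames = 1, seed = 87, noise_sd = 0))
  img <- get_frame(ph$series, 1)$data
  bg <- img[ph$truth_masks[[1]]$data == 0]
  expect_gt(mean(bg > 50), 0.9) # no black background
  expect_gt(sd(bg), 80) # varied, high-contrast structure
  # brain intensity band overlaps the maternal intensity range
  br <- img[ph$truth_masks[[1]]$data == 1]
  expect_gt(max(bg), min(br))
})

test_that("the aliasing ghost adds an attenuated brain copy half a FOV away", {
  base <- generate_phantom(phantom_spec(n_frames = 1, seed = 88, noise_sd = 0))
  gh <- generate_phantom(phantom_spec(n_frames = 1, seed = 88, noise_sd = 0,
                                      ghost_fraction = 0.5))
  diffimg <- gh$series$data[, , , 1] - base$series$data[, , , 1]
  m <- base$truth_masks[[1]]$data
  d2 <- dim(m)[2]
  shifted <- m[, c((d2 / 2 + 1):d2, 1:(d2 / 2)), ]
  expect_gt(mean(diffimg[shifted == 1]), 100) # ghost sits under the shifted mask
  expect_lt(mean(abs(diffimg[shifted == 0 & m == 0])), 1)
})

test_that("datasets split subjects disjointly at the requested sizes", {
  ds <- make_dataset(30, fractions = c(train = 2 / 3, val = 1 / 6, test = 1 / 6),
                     seed = 3)
  expect_equal(lengths(ds$splits)[c("train", "val", "test")],
               c(train = 20L, val = 5L, test = 5L))
  expect_length(Reduce(intersect, ds$splits), 0)
  expect_equal(sort(unlist(ds$splits, use.names = FALSE)), sort(ds$manifest$subject))
  expect_error(make_dataset(2, fractions = c(train = .5, val = .25, test = .25)),
               "too small")
})

test_that("pseudo-age maps monotonically to brain size", {
  ages <- c(24, 30, 39)
  axes <- vapply(ages, function(a) phantom_spec(pseudo_age_weeks = a)$brain_axes_mm[1], 0)
  expect_true(all(diff(axes) > 0))
  vols <- vapply(ages, function(a) {
    sum(generate_phantom(phantom_spec(n_frames = 1, seed = 89,
                                      pseudo_age_weeks = a))$truth_masks[[1]]$data)
  }, 0)
  expect_true(all(diff(vols) > 0))
})

test_that("dataset export writes a BIDS-style tree with manifest", {
  ds <- make_dataset(3, fractions = c(train = 1 / 3, val = 1 / 3, test = 1 / 3),
                     seed = 5, n_frames = 2,
                     grid_shape = c(24, 24, 12), spacing = c(6, 6, 6))
  d <- withr::local_tempdir()
  write_dataset(ds, d)
  expect_true(file.exists(file.path(d, "sub-01", "func", "sub-01_task-rest_bold.nii.gz")))
  expect_true(file.exists(file.path(d, "sub-02", "func", "sub-02_frame-001_mask.nii.gz")))
  expect_true(file.exists(file.path(d, "manifest.yaml")))
  y <- yaml::read_yaml(file.path(d, "manifest.yaml"))
  expect_length(y$subjects, 3)
  s <- read_series(file.path(d, "sub-01", "func", "sub-01_task-rest_bold.nii.gz"))
  expect_equal(n_frames(s), 2)
})

test_that("increasing ghost fraction does not improve trained-model Dice", {
  fit <- toy_fit()
  mean_dice <- vapply(c(0, 0.35, 0.7), function(g) {
    mean(vapply(90:92, function(s) {
      ph <- generate_phantom(phantom_spec(n_frames = 1, seed = s, ghost_fraction = g))
      std <- standardize_volume(get_frame(ph$series, 1), toy_grid())
      prob <- predict_probability(fit$model, std$volume)
      msk <- suppressWarnings(binarize_mask(prob))
      native <- invert_standardization(msk, std$record)
      compute_metrics(native, ph$truth_masks[[1]])$dice
    }, 0))
  }, 0)
  expect_true(all(diff(mean_dice) <= 1e-8))
})
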