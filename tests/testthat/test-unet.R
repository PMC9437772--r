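test_that("network architecture honours the slice-segmentation contract", {
  cfg <- unet_config() # depth 4, base 32, 96 x 96
  model <- build_unet(cfg, seed = 1)
  # final 1x1 layer maps to one channel per class
  expect_equal(ncol(model$params$final$w), 2L)
  expect_equal(nrow(model$params$final$w), cfg$base_filters)
  # spatial dims preserved through the full forward pass
  x <- array(runif(96 * 96), c(96, 96, 1, 1))
  logits <- fetalmask:::unet_forward(model, x)$logits
  expect_equal(dim(logits), c(96L, 96L, 2L, 1L))
  # doubling base_filters doubles every hidden level's width; the image
  # input (1 channel) and class output (2 channels) are fixed
  p1 <- fetalmask:::unet_layer_plan(unet_config(depth = 3, base_filters = 8))
  p2 <- fetalmask:::unet_layer_plan(unet_config(depth = 3, base_filters = 16))
  for (nm in setdiff(names(p1), "final"))
    expect_equal(2 * p1[[nm]][2], p2[[nm]][2])
  expect_equal(p2$final[2], p1$final[2])
  expect_error(unet_config(depth = 4, in_shape = c(100, 100)), "divisible")
})

test_that("backpropagated gradients match central finite differences", {
  cfg <- unet_config(depth = 2, base_filters = 2, in_shape = c(8, 8))
  model <- build_unet(cfg, seed = 2)
  set.seed(3)
  # jitter biases away from zero: zero-initialized biases leave conv
  # preactivations exactly at the ReLU kink over zero-input patches, where
  # finite differences and the subgradient legitimately disagree
  for (nm in names(model$params))
    model$params[[nm]]$b <- model$params[[nm]]$b +
      rnorm(length(model$params[[nm]]$b), 0, 0.05)
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 1, 2))
  y <- array(rbinom(8 * 8 * 2, 1, 0.4), c(8, 8, 1, 2))
  fwd <- fetalmask:::unet_forward(model, x, cache = TRUE)
  ce <- fetalmask:::softmax_ce(fwd$logits, y)
  gr <- fetalmask:::unet_backward(model, fwd$cache, ce$dlogits)
  loss_at <- function(m) fetalmask:::softmax_ce(fetalmask:::unet_forward(m, x)$logits, y)$loss
  h <- 1e-5
  for (nm in names(model$params)) {
    for (idx in list(c(1, 1), c(nrow(model$params[[nm]]$w), 1))) {
      up <- model; up$params[[nm]]$w[idx[1], idx[2]] <- up$params[[nm]]$w[idx[1], idx[2]] + h
      dn <- model; dn$params[[nm]]$w[idx[1], idx[2]] <- dn$params[[nm]]$w[idx[1], idx[2]] - h
      num <- (loss_at(up) - loss_at(dn)) / (2 * h)
      expect_equal(gr[[nm]]$w[idx[1], idx[2]], num, tolerance = 1e-4)
    }
    up <- model; up$params[[nm]]$b[1] <- up$params[[nm]]$b[1] + h
    dn <- model; dn$params[[nm]]$b[1] <- dn$params[[nm]]$b[1] - h
    expect_equal(gr[[nm]]$b[1], (loss_at(up) - loss_at(dn)) / (2 * h), tolerance = 1e-4)
  }
})

test_that("volumes slice into ordered axial planes and restack exactly", {
  v <- volume3d(array(rnorm(96 * 96 * 37), c(96, 96, 37)), c(3, 3, 3))
  s <- slice_volume(v)
  expect_equal(dim(s), c(96L, 96L, 1L, 37L))
  expect_identical(s[, , 1, 12], v$data[, , 12]) # slice k is plane k
  expect_identical(restack_slices(s), v$data)
})

test_that("dihedral augmentation forms a group and preserves mask counts", {
  set.seed(4)
  x <- array(rnorm(12 * 12 * 5), c(12, 12, 5))
  m <- array(rbinom(12 * 12 * 5, 1, 0.2), c(12, 12, 5))
  expect_identical(dihedral_transform(x, 0), x) # identity element
  r4 <- x
  for (i in 1:4) r4 <- dihedral_transform(r4, 1)
  expect_identical(r4, x) # quarter-turn has order 4
  ff <- dihedral_transform(dihedral_transform(x, 4), 4)
  expect_identical(ff, x) # flip has order 2
  for (el in 0:7) {
    aug <- augment_pair(x, m, el)
    expect_equal(sum(aug$y), sum(m)) # voxel permutation
    # the same in-plane transform applied to every slice
    expect_identical(aug$x[, , 3], dihedral_transform(x[, , 3], el))
  }
})

test_that("learning-rate schedule is the staircase eta0 * gamma^floor(t/K)", {
  cfg <- training_config() # 1e-4, 0.9, every 10000
  expect_identical(learning_rate(cfg, 0), 1e-4)
  expect_equal(learning_rate(cfg, 10000), 9e-5)
  expect_equal(learning_rate(cfg, 25000), 8.1e-5)
  t <- 0:30000
  lr <- learning_rate(cfg, t)
  expect_true(all(diff(lr) <= 0)) # non-increasing
  expect_equal(length(unique(lr)), 4) # piecewise constant with period K
})

test_that("predicted probabilities form a per-voxel 2-class distribution", {
  model <- build_unet(toy_net(), seed = 5)
  v <- volume3d(array(runif(32 * 32 * 16), c(32, 32, 16)), c(9, 9, 7))
  p <- predict_probability(model, v)
  expect_true(all(p$data >= 0 & p$data <= 1))
  # complement channel: probabilities sum to 1
  logits <- fetalmask:::unet_forward(model, slice_volume(v))$logits
  sm <- fetalmask:::softmax2(logits)
  expect_true(all(abs(sm[, , 1, ] + sm[, , 2, ] - 1) < 1e-5))
  # determinism of prediction
  expect_identical(p$data, predict_probability(model, v)$data)
  wrong <- volume3d(array(0, c(16, 16, 4)), c(9, 9, 7))
  expect_error(predict_probability(model, wrong), "shape")
})
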