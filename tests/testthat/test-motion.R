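make_trace <- function(params) {
  tb <- tibble::as_tibble(as.data.frame(params))
  names(tb) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  tb <- dplyr::mutate(tb, frame = dplyr::row_number() - 1L, .before = 1)
  attr(tb, "center") <- c(0, 0, 0)
  class(tb) <- c("realignment_trace", class(tb))
  tb
}

test_that("framewise displacement follows the translation + arc formula", {
  z <- rbind(rep(0, 6), rep(0, 6))
  expect_equal(framewise_displacement(make_trace(z)), 0)
  tr <- rbind(rep(0, 6), c(1, 0, 0, 0, 0, 0)) # 1 mm x-translation
  expect_equal(framewise_displacement(make_trace(tr)), 1)
  ro <- rbind(rep(0, 6), c(0, 0, 0, 0.02, 0, 0)) # 0.02 rad at 50 mm radius
  expect_equal(framewise_displacement(make_trace(ro), radius_mm = 50), 1)
  expect_equal(framewise_displacement(make_trace(ro), radius_mm = 25), 0.5)
})

test_that("FD is invariant to the choice of common reference", {
  set.seed(21)
  params <- matrix(c(runif(15, -3, 3), runif(15, -0.1, 0.1)), 5, 6)
  fd1 <- framewise_displacement(make_trace(params))
  # re-anchor every transform on frame 3
  ctr <- c(0, 0, 0)
  anchor <- solve(rigid_matrix(params[3, ], ctr))
  re <- t(apply(params, 1, function(p)
    as.numeric(rigid_parameters(rigid_matrix(p, ctr) %*% anchor, ctr))))
  fd2 <- framewise_displacement(make_trace(re))
  expect_equal(fd1, fd2, tolerance = 1e-9)
})

test_that("censoring removes exactly the frames whose incoming FD exceeds the threshold", {
  cm <- censor_frames(c(0, 0.2, 5.0, 0.1), threshold_mm = 0.5, tr_seconds = 2)
  expect_equal(sum(!cm$keep), 1)
  expect_equal(which(!cm$keep), 4L) # FD(3)=5.0 censors the frame it leads into
  all_kept <- censor_frames(rep(0.1, 359), threshold_mm = 10, tr_seconds = 2)
  expect_equal(sum(all_kept$keep), 360)
  expect_equal(all_kept$minutes_retained, 12) # 360 frames at TR 2 s
})

test_that("censored count is monotone non-increasing across the threshold sweep", {
  set.seed(22)
  fd <- abs(rnorm(50, 1, 1.2))
  sw <- fd_sweep(fd, thresholds_mm = seq(0.5, 3.8, by = 0.3), tr_seconds = 2)
  expect_true(all(diff(sw$frames_censored) <= 0))
  expect_true(all(diff(sw$minutes_retained) >= 0))
  expect_equal(sw$frames_kept + sw$frames_censored, rep(51, nrow(sw)))
})

test_that("registering a volume to itself returns the identity", {
  ph <- generate_phantom(phantom_spec(n_frames = 1, seed = 61))
  v <- apply_mask(get_frame(ph$series, 1), ph$truth_masks[[1]])
  tr <- register_rigid(v, v)
  expect_lte(max(abs(as.numeric(tr)[1:3])), 0.05)
  expect_lte(max(abs(as.numeric(tr)[4:6])), 0.001)
})

test_that("a known translation is recovered within 0.25 mm", {
  ph <- generate_phantom(phantom_spec(n_frames = 1, seed = 62, noise_sd = 10))
  v <- apply_mask(get_frame(ph$series, 1), ph$truth_masks[[1]])
  truth <- rigid_transform(2, -1, 0)
  M <- rigid_matrix(truth, fetalmask:::world_center(v))
  mov <- v
  mov$data <- resample_volume(v, dim(v$data), v$affine, world = solve(M))
  est <- register_rigid(mov, v)
  expect_lt(max(abs(as.numeric(est)[1:3] - c(2, -1, 0))), 0.25)
})

test_that("a known 5-degree in-plane rotation is recovered within 0.5 degrees", {
  ph <- generate_phantom(phantom_spec(n_frames = 1, seed = 63, noise_sd = 10))
  v <- apply_mask(get_frame(ph$series, 1), ph$truth_masks[[1]])
  truth <- rigid_transform(0, 0, 0, 0, 0, 5 * pi / 180)
  M <- rigid_matrix(truth, fetalmask:::world_center(v))
  mov <- v
  mov$data <- resample_volume(v, dim(v$data), v$affine, world = solve(M))
  est <- register_rigid(mov, v)
  expect_lt(abs(as.numeric(est)[6] - 5 * pi / 180) * 180 / pi, 0.5)
})

test_that("constant images register to identity with a warning", {
  flat <- volume3d(array(1, c(10, 10, 6)), c(3, 3, 3))
  expect_warning(tr <- register_rigid(flat, flat), "constant")
  expect_equal(as.numeric(tr), rep(0, 6))
})

test_that("sequential realignment recovers an injected trajectory", {
  ph <- generate_phantom(phantom_spec(n_frames = 10, quiescent_frames = c(3, 5),
                                      seed = 64))
  masked <- apply_mask_series(ph$series, ph$truth_masks)
  re <- realign_series(masked)
  est <- as.matrix(re$trace[, c("tx", "ty", "tz", "rx", "ry", "rz")])
  tru <- as.matrix(ph$truth_motion[, c("tx", "ty", "tz", "rx", "ry", "rz")])
  # bounds reflect the phantom's intrinsic registration floor: the binary
  # mask silhouette is voxelized independently at each pose, which limits
  # rotation recovery on large jumps to a few tenths of a degree
  expect_lt(sqrt(mean((est[, 1:3] - tru[, 1:3])^2)), 0.2) # mm RMS
  expect_lt(sqrt(mean((est[, 4:6] - tru[, 4:6])^2)) * 180 / pi, 0.8) # deg RMS
  expect_equal(as.numeric(unlist(re$trace[1, c("tx", "ty", "tz", "rx", "ry", "rz")])),
               rep(0, 6)) # reference frame transform is the identity
  expect_length(re$fd_mm, 9)
  expect_true(all(re$fd_mm >= 0))
})

test_that("motion outputs are written as 6-column text plus FD series", {
  params <- rbind(rep(0, 6), c(1, 0, 0, 0.01, 0, 0), c(0.5, -0.2, 0.1, 0, 0, 0))
  trace <- make_trace(params)
  fd <- framewise_displacement(trace)
  d <- withr::local_tempdir()
  write_motion_outputs(trace, fd, d)
  mat <- as.matrix(read.table(file.path(d, "realignment_parameters.txt")))
  expect_equal(dim(mat), c(3L, 6L))
  expect_equal(unname(mat), unname(params), tolerance = 1e-6)
  expect_length(readLines(file.path(d, "framewise_displacement.txt")), 2)
})
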