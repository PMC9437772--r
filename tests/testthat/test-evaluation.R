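test_that("confusion counts partition the grid", {
  d <- c(10, 10, 10)
  ref <- array(0, d); ref[1:5, 1:5, 1:4] <- 1 # 100 voxels
  cc <- confusion(ref, ref)
  expect_equal(unlist(cc), c(tp = 100, fp = 0, fn = 0, tn = 900))
  empty <- array(0, d)
  cc2 <- confusion(empty, ref)
  expect_equal(cc2$fn, 100)
  set.seed(1)
  a <- array(rbinom(prod(d), 1, 0.3), d); b <- array(rbinom(prod(d), 1, 0.3), d)
  cc3 <- confusion(a, b)
  expect_equal(cc3$tp + cc3$fp + cc3$fn + cc3$tn, prod(d))
})

test_that("metrics match hand-computable geometry", {
  d <- c(12, 12, 6)
  ident <- array(0, d); ident[4:8, 4:8, 2:4] <- 1
  m <- compute_metrics(ident, ident, spacing = c(3, 3, 3))
  expect_equal(m$dice, 1); expect_equal(m$jaccard, 1)
  expect_equal(m$hausdorff_mm, 0)
  expect_equal(m$sensitivity, 1); expect_equal(m$specificity, 1)

  a <- array(0, d); a[2:4, 2:4, 1:2] <- 1
  b <- array(0, d); b[8:10, 8:10, 4:5] <- 1
  m2 <- compute_metrics(a, b, spacing = c(3, 3, 3))
  expect_equal(m2$dice, 0); expect_equal(m2$jaccard, 0)

  # single voxels 3 apart along one axis at 3 mm -> 9 mm
  p1 <- array(0, d); p1[2, 2, 2] <- 1
  p2 <- array(0, d); p2[5, 2, 2] <- 1
  expect_equal(compute_metrics(p1, p2, spacing = c(3, 3, 3))$hausdorff_mm, 9)

  # 2x2x1 block vs the same block shifted one voxel in-plane
  q1 <- array(0, d); q1[2:3, 2:3, 2] <- 1
  q2 <- array(0, d); q2[3:4, 2:3, 2] <- 1
  m3 <- compute_metrics(q1, q2, spacing = c(1, 1, 1))
  o <- oracle_metrics(q1, q2)
  expect_equal(m3$dice, 0.5); expect_equal(m3$jaccard, 1 / 3)
  expect_equal(m3$dice, o$dice); expect_equal(m3$jaccard, o$jaccard)
})

test_that("all five metrics agree exactly with brute-force oracles", {
  set.seed(9)
  n_checked <- 0
  for (i in 1:100) {
    d <- sample(6:16, 3, replace = TRUE)
    a <- random_mask(d, n_seeds = sample(1:3, 1))
    b <- random_mask(d, n_seeds = sample(1:3, 1))
    if (sum(a) == 0 || sum(b) == 0) next
    sp <- sample(c(1, 2, 3), 3, replace = TRUE)
    m <- compute_metrics(a, b, spacing = sp)
    o <- oracle_metrics(a, b)
    expect_identical(m$dice, o$dice)
    expect_identical(m$jaccard, o$jaccard)
    expect_identical(m$sensitivity, o$sensitivity)
    expect_identical(m$specificity, o$specificity)
    expect_equal(m$hausdorff_mm, oracle_hausdorff(a, b, sp), tolerance = 1e-12)
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 80)
})

test_that("Jaccard equals D/(2-D) to 1e-12 on every evaluated pair", {
  set.seed(10)
  for (i in 1:25) {
    d <- sample(6:14, 3, replace = TRUE)
    a <- random_mask(d); b <- random_mask(d)
    if (sum(a) == 0 || sum(b) == 0) next
    m <- compute_metrics(a, b)
    expect_equal(m$jaccard, m$dice / (2 - m$dice), tolerance = 1e-12)
    expect_lte(m$jaccard, m$dice)
  }
})

test_that("Dice is symmetric; sensitivity and specificity swap roles", {
  set.seed(11)
  a <- random_mask(c(10, 10, 8)); b <- random_mask(c(10, 10, 8))
  m_ab <- compute_metrics(a, b); m_ba <- compute_metrics(b, a)
  expect_equal(m_ab$dice, m_ba$dice)
  expect_equal(m_ab$hausdorff_mm, m_ba$hausdorff_mm)
  ca <- confusion(a, b); cb <- confusion(b, a)
  expect_equal(ca$fp, cb$fn); expect_equal(ca$fn, cb$fp)
})

test_that("degenerate empty-mask conventions hold", {
  d <- c(8, 8, 8)
  e <- array(0, d); f <- array(0, d); f[3:5, 3:5, 3:5] <- 1
  expect_message(m1 <- compute_metrics(e, e), "both masks empty")
  expect_equal(m1$dice, 1); expect_equal(m1$hausdorff_mm, 0)
  expect_message(m2 <- compute_metrics(e, f, spacing = c(1, 1, 1)), "one mask empty")
  expect_equal(m2$dice, 0)
  expect_equal(m2$hausdorff_mm, sqrt(sum((c(7, 7, 7))^2))) # grid diagonal
})

test_that("specificity dominates Dice on sparse-foreground grids", {
  set.seed(12)
  for (i in 1:8) {
    a <- random_ellipsoid(c(20, 20, 14), c(3, 3, 3), min_vox = 60)$data
    b <- random_ellipsoid(c(20, 20, 14), c(3, 3, 3), min_vox = 60)$data
    if (mean(a) > 0.1 || mean(b) > 0.1) next
    m <- compute_metrics(a, b)
    expect_gte(m$specificity, m$dice)
  }
})

test_that("subject aggregation averages volumes within subject", {
  tbl <- dplyr::bind_rows(
    tibble::tibble(subject = "s1", volume_id = c("a", "b"), dice = c(0.9, 1.0),
                   jaccard = 0.9, hausdorff_mm = 1, sensitivity = 0.9, specificity = 1),
    tibble::tibble(subject = "s2", volume_id = c("c", "d", "e"), dice = c(0.8, 0.8, 0.8),
                   jaccard = 0.7, hausdorff_mm = 2, sensitivity = 0.8, specificity = 1))
  agg <- aggregate_by_subject(tbl)
  expect_equal(agg$by_subject$dice[agg$by_subject$subject == "s1"], 0.95)
  expect_equal(agg$by_subject$dice[agg$by_subject$subject == "s2"], 0.8)
  expect_equal(agg$per_volume$dice, mean(tbl$dice)) # grand per-volume mean
  expect_equal(agg$per_volume$n_volumes, 5L)
})

test_that("low-Dice flagging respects the threshold", {
  tbl <- tibble::tibble(subject = c("s1", "s1", "s2"), volume_id = c("a", "b", "c"),
                        dice = c(0.95, 0.87, 0.91), jaccard = 0.8,
                        hausdorff_mm = 1, sensitivity = 0.9, specificity = 1)
  expect_equal(nrow(flag_low_dice(tbl)), 1)
  expect_equal(flag_low_dice(tbl)$volume_id, "b")
  expect_equal(nrow(flag_low_dice(tbl, threshold = 0)), 0)
  expect_equal(nrow(flag_low_dice(tbl, threshold = 1)), 3)
})

test_that("directory evaluation pairs files and writes the metrics CSV", {
  pd <- withr::local_tempdir(); rd <- withr::local_tempdir()
  set.seed(13)
  for (f in c("s1_v1.nii.gz", "s2_v1.nii.gz")) {
    m <- random_ellipsoid(c(10, 10, 8), c(3, 3, 3), min_vox = 30)
    write_mask(m, file.path(rd, f))
    write_mask(m, file.path(pd, f))
  }
  csv <- withr::local_tempfile(fileext = ".csv")
  out <- evaluate_mask_dirs(pd, rd, out_csv = csv)
  expect_equal(nrow(out), 2)
  expect_equal(out$subject, c("s1", "s2"))
  expect_true(all(out$dice == 1))
  expect_true(file.exists(csv))
})
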