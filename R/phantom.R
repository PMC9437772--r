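#' Synthetic fetal fMRI phantom specification
#'
#' The phantom reproduces the image characteristics that make fetal EPI
#' hard to mask: a bright, textured ellipsoidal "brain" of arbitrary
#' orientation embedded in a filled maternal compartment (no black
#' background) whose structures have high-contrast boundaries and varied
#' intensity, a bright abdominal rim, rigid inter-volume motion
#' alternating quiescent stretches with jumps, EPI-like additive noise,
#' and an optional half-FOV aliasing ghost of the brain. All intensities
#' are arbitrary units in roughly [0, 1000].
#'
#' Brain size scales with a pseudo-gestational-age parameter: the
#' semi-axes are `c(40, 33, 27) * pseudo_age_weeks / 30` mm (about 150
#' cm^3 at 30 weeks, matching fetal brain volume at that age).
#'
#' @param grid_shape,spacing native acquisition grid (default 80x80x32 at
#'   3.4 mm, whose extent fits inside the standard network grid).
#' @param pseudo_age_weeks drives brain size (study range 24-39 weeks).
#' @param orientation brain orientation angles (radians); NULL = random.
#' @param center_offset_mm brain centre offset from the grid centre;
#'   NULL = random within the margin that keeps the brain in the grid.
#' @param n_structures number of high-contrast maternal blobs.
#' @param noise_sd additive Gaussian noise s.d. (a.u.).
#' @param ghost_fraction aliasing ghost amplitude in `[0, 1]` (0 = none).
#' @param jump_trans_mm,jump_rot_deg bounds of the per-jump pose (frames
#'   move within +/- these values).
#' @param jitter_sd_mm s.d. of the small within-quiescent-period pose
#'   jitter (0 gives a perfectly still brain between jumps).
#' @param quiescent_frames range of quiescent-run lengths between jumps.
#' @param n_frames,tr_seconds series length and repetition time.
#' @param seed RNG seed; the seed fully determines the phantom.
#' @param subject subject identifier.
#' @export
phantom_spec <- function(grid_shape = c(80, 80, 32), spacing = c(3.4, 3.4, 3.4),
                         pseudo_age_weeks = 30, orientation = NULL,
                         center_offset_mm = NULL, n_structures = 12,
                         noise_sd = 25, ghost_fraction = 0,
                         jump_trans_mm = 4, jump_rot_deg = 6,
                         jitter_sd_mm = 0.03,
                         quiescent_frames = c(6, 15), n_frames = 20,
                         tr_seconds = 2, seed = 1, subject = "sub-01") {
  stopifnot(pseudo_age_weeks > 0, ghost_fraction >= 0, ghost_fraction <= 1,
            n_frames >= 1, noise_sd >= 0)
  structure(list(grid_shape = as.integer(grid_shape),
                 spacing = rep_len(as.numeric(spacing), 3),
                 pseudo_age_weeks = pseudo_age_weeks,
                 brain_axes_mm = c(40, 33, 27) * pseudo_age_weeks / 30,
                 orientation = orientation, center_offset_mm = center_offset_mm,
                 n_structures = as.integer(n_structures), noise_sd = noise_sd,
                 ghost_fraction = ghost_fraction, jump_trans_mm = jump_trans_mm,
                 jump_rot_deg = jump_rot_deg, jitter_sd_mm = jitter_sd_mm,
                 quiescent_frames = quiescent_frames,
                 n_frames = as.integer(n_frames), tr_seconds = tr_seconds,
                 seed = as.integer(seed), subject = subject),
            class = "phantom_spec")
}

# Smooth seed-determined texture: a small sum of random 3D cosines,
# evaluated analytically so it moves rigidly with the object.
cosine_texture <- function(n_terms, amp_range, wavelength_range_mm) {
  list(amp = stats::runif(n_terms, amp_range[1], amp_range[2]),
       k = matrix(stats::rnorm(3 * n_terms), 3) |>
         apply(2, function(v) v / sqrt(sum(v^2))) *
         rep(2 * pi / stats::runif(n_terms, wavelength_range_mm[1], wavelength_range_mm[2]),
             each = 3),
       phase = stats::runif(n_terms, 0, 2 * pi))
}

eval_texture <- function(tex, xyz) {
  out <- numeric(nrow(xyz))
  for (j in seq_along(tex$amp))
    out <- out + tex$amp[j] * cos(xyz %*% tex$k[, j, drop = FALSE] + tex$phase[j])
  out
}

#' Generate a synthetic fetal fMRI subject
#'
#' Frame 0 composites the textured brain ellipsoid into the maternal
#' compartment; each later frame applies that frame's rigid pose to the
#' brain and its mask only (the maternal compartment is static), then
#' adds the optional ghost and noise. The per-frame ground-truth mask is
#' the analytically moved ellipsoid (no interpolation error), and the
#' ground-truth motion is returned both as transforms and as a tibble.
#'
#' @param spec a [phantom_spec()].
#' @return a `phantom` object: `series` ([time_series4d()]),
#'   `truth_masks` (list of binary `volume3d`), `truth_motion` (tibble),
#'   `transforms` (list of [rigid_transform()]), `template` (clean,
#'   motionless `volume3d`), `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  d <- spec$grid_shape; sp <- spec$spacing
  affine <- centered_affine(d, sp)
  half_ext <- (d - 1) / 2 * sp
  ax <- lapply(1:3, function(i) (seq_len(d[i]) - 1 - (d[i] - 1) / 2) * sp[i])
  xyz <- cbind(rep(ax[[1]], times = d[2] * d[3]),
               rep(rep(ax[[2]], each = d[1]), times = d[3]),
               rep(ax[[3]], each = d[1] * d[2]))

  # --- static maternal compartment -------------------------------------
  mat_tex <- cosine_texture(8, c(30, 80), c(20, 60))
  maternal <- 280 + eval_texture(mat_tex, xyz)
  for (b in seq_len(spec$n_structures)) {
    ctr <- stats::runif(3, -0.8, 0.8) * half_ext
    sg <- stats::runif(3, 8, 25)
    amp <- stats::runif(1, -200, 700)
    q <- sweep(xyz, 2, ctr)
    maternal <- maternal + amp * exp(-0.5 * (q^2 %*% (1 / sg^2)))
  }
  rho <- sqrt((xyz^2) %*% (1 / half_ext^2)) # bright abdominal rim
  maternal <- maternal + 620 * exp(-((rho - 0.92) / 0.06)^2)
  maternal <- pmax(maternal, 0)

  # --- brain anatomy ----------------------------------------------------
  a <- spec$brain_axes_mm
  R0 <- if (is.null(spec$orientation)) rot3(stats::runif(1, -pi, pi),
                                            stats::runif(1, -pi, pi),
                                            stats::runif(1, -pi, pi))
        else rot3(spec$orientation[1], spec$orientation[2], spec$orientation[3])
  radius <- sqrt((R0^2) %*% a^2) # support radius of the rotated ellipsoid per axis
  c0 <- if (is.null(spec$center_offset_mm)) {
    marg <- pmax(0, half_ext - radius - spec$jump_trans_mm - 2)
    stats::runif(3, -1, 1) * pmin(15, marg)
  } else spec$center_offset_mm
  brain_tex <- cosine_texture(5, c(25, 65), c(15, 40))

  # --- motion trajectory ------------------------------------------------
  poses <- matrix(0, spec$n_frames, 6)
  i <- 1
  current <- numeric(6)
  while (i <= spec$n_frames) {
    len <- sample(seq(spec$quiescent_frames[1], spec$quiescent_frames[2]), 1)
    for (k in seq_len(len)) {
      if (i > spec$n_frames) break
      jit <- c(stats::rnorm(3, 0, spec$jitter_sd_mm),
               stats::rnorm(3, 0, spec$jitter_sd_mm / 60))
      poses[i, ] <- if (i == 1) numeric(6) else current + jit
      i <- i + 1
    }
    # jump amplitude drawn uniformly within the stated range; the pose is
    # kept within the same absolute bounds so the brain stays in the FOV
    bound <- c(rep(spec$jump_trans_mm, 3), rep(spec$jump_rot_deg * pi / 180, 3))
    if (any(bound > 0)) {
      repeat {
        delta <- c(stats::runif(3, -spec$jump_trans_mm, spec$jump_trans_mm),
                   stats::runif(3, -1, 1) * spec$jump_rot_deg * pi / 180)
        cand <- current + delta
        if (all(abs(cand) <= bound + 1e-12)) break
      }
      current <- cand
    }
  }

  # --- frames -----------------------------------------------------------
  nvox <- prod(d)
  arr <- array(0, c(d, spec$n_frames))
  masks <- vector("list", spec$n_frames)
  transforms <- vector("list", spec$n_frames)
  shift2 <- as.integer(round(d[2] / 2))
  clean0 <- NULL
  for (n in seq_len(spec$n_frames)) {
    pose <- rigid_transform(poses[n, 1], poses[n, 2], poses[n, 3],
                            poses[n, 4], poses[n, 5], poses[n, 6])
    transforms[[n]] <- pose
    Pinv <- solve(rigid_matrix(pose)) # world centre of the grid is the origin
    xw <- sweep(xyz %*% t(Pinv[1:3, 1:3]), 2, -Pinv[1:3, 4])
    u <- sweep(xw, 2, c0) %*% R0 # brain-local coordinates
    inside <- as.numeric((u^2 %*% (1 / a^2)) <= 1)
    brain <- pmax(50, 650 + eval_texture(brain_tex, u))
    img <- maternal * (1 - inside) + brain * inside
    if (n == 1) clean0 <- img
    if (spec$ghost_fraction > 0) {
      gsrc <- array(brain * inside, d)
      idx <- c((shift2 + 1):d[2], 1:shift2) # half-FOV wrap along phase axis
      img <- img + spec$ghost_fraction * as.vector(gsrc[, idx, ])
    }
    if (spec$noise_sd > 0) img <- img + stats::rnorm(nvox, 0, spec$noise_sd)
    arr[, , , n] <- img
    masks[[n]] <- volume3d(array(as.numeric(inside), d), sp, affine,
                           frame_index = n - 1L)
  }

  motion <- tibble::tibble(frame = seq_len(spec$n_frames) - 1L,
                           tx = poses[, 1], ty = poses[, 2], tz = poses[, 3],
                           rx = poses[, 4], ry = poses[, 5], rz = poses[, 6])
  structure(list(series = time_series4d(arr, sp, affine, tr_seconds = spec$tr_seconds),
                 truth_masks = masks, truth_motion = motion,
                 transforms = transforms,
                 template = volume3d(array(clean0, d), sp, affine),
                 anatomy = list(R0 = R0, center = c0, axes = a),
                 spec = spec),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %s, %d frames, pseudo-age %.1f w, ghost %.2f, noise sd %.0f\n",
              x$spec$subject, x$spec$n_frames, x$spec$pseudo_age_weeks,
              x$spec$ghost_fraction, x$spec$noise_sd))
  invisible(x)
}

#' Evaluate a phantom's exact ground-truth mask on an arbitrary grid
#'
#' The phantom's brain is analytic (a posed ellipsoid), so its mask can be
#' rendered exactly on any voxel grid - unlike nearest-neighbour
#' resampling of the native mask, which aliases the boundary. Used to
#' produce clean training labels on the network's standard grid.
#'
#' @param ph a `phantom`.
#' @param frame 1-based frame number (selects the pose).
#' @param target a [volume3d()] whose dims and affine define the grid.
#' @return a binary `volume3d` on the target grid.
#' @export
phantom_mask_on <- function(ph, frame, target) {
  stopifnot(inherits(ph, "phantom"), inherits(target, "volume3d"))
  an <- ph$anatomy
  d <- dim(target$data)
  vox <- as.matrix(expand.grid(0:(d[1] - 1), 0:(d[2] - 1), 0:(d[3] - 1)))
  xyz <- vox %*% t(target$affine[1:3, 1:3])
  xyz <- sweep(xyz, 2, -target$affine[1:3, 4])
  Pinv <- solve(rigid_matrix(ph$transforms[[frame]]))
  xw <- sweep(xyz %*% t(Pinv[1:3, 1:3]), 2, -Pinv[1:3, 4])
  u <- sweep(xw, 2, an$center) %*% an$R0
  inside <- as.numeric((u^2 %*% (1 / an$axes^2)) <= 1)
  volume3d(array(inside, d), target$spacing, target$affine,
           frame_index = frame - 1L)
}

#' Subject-level phantom dataset with train/validation/test splits
#'
#' Draws one spec per subject (pseudo-age uniform over the study range,
#' random orientation, offset and motion) and assigns subjects to
#' disjoint splits. Phantoms themselves are generated on demand with
#' [generate_phantom()]; the manifest records every spec.
#'
#' @param n_subjects total number of subjects.
#' @param fractions named fractions (train, val, test) summing to 1.
#' @param seed base seed; per-subject seeds derive from it.
#' @param n_frames frames per subject.
#' @param spec_sampler optional `function(subject, seed)` returning a
#'   [phantom_spec()]; replaces the default sampler.
#' @param ... passed to [phantom_spec()] by the default sampler.
#' @return a `phantom_dataset`: list with `specs` (named by subject),
#'   `manifest` (tibble: subject, split, pseudo_age_weeks, seed) and
#'   `splits` (list of subject-id vectors).
#' @export
make_dataset <- function(n_subjects, fractions = c(train = 2/3, val = 1/6, test = 1/6),
                         seed = 1, n_frames = 4, spec_sampler = NULL, ...) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8, all(fractions >= 0))
  counts <- floor(fractions * n_subjects)
  rem <- n_subjects - sum(counts)
  if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1
  if (any(fractions > 0 & counts == 0))
    stop("n_subjects too small for the requested split fractions")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ids <- sprintf("sub-%02d", seq_len(n_subjects))
  assignment <- sample(rep(names(counts), counts))
  sub_seeds <- (as.numeric(seed) * 7919 + seq_len(n_subjects) * 104729) %% 2147483647
  ages <- stats::runif(n_subjects, 24, 39)
  specs <- lapply(seq_len(n_subjects), function(i) {
    if (!is.null(spec_sampler)) spec_sampler(ids[i], as.integer(sub_seeds[i]))
    else phantom_spec(pseudo_age_weeks = ages[i], n_frames = n_frames,
                      seed = as.integer(sub_seeds[i]), subject = ids[i], ...)
  })
  names(specs) <- ids
  manifest <- tibble::tibble(
    subject = ids, split = assignment,
    pseudo_age_weeks = vapply(specs, `[[`, 0, "pseudo_age_weeks"),
    seed = vapply(specs, `[[`, 0L, "seed"))
  structure(list(specs = specs, manifest = manifest,
                 splits = split(ids, assignment)),
            class = "phantom_dataset")
}

#' @export
print.phantom_dataset <- function(x, ...) {
  cat(sprintf("<phantom_dataset> %d subjects (%s)\n", nrow(x$manifest),
              paste(sprintf("%s: %d", names(x$splits),
                            lengths(x$splits)), collapse = ", ")))
  invisible(x)
}

#' Write a phantom dataset as a BIDS-style NIFTI tree
#'
#' Emits per-subject `func` BOLD series, ground-truth masks, the true
#' motion as CSV, and a dataset manifest as YAML.
#'
#' @param dataset a `phantom_dataset`.
#' @param dir output directory.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(dataset$specs)) {
    ph <- generate_phantom(dataset$specs[[id]])
    sd <- file.path(dir, id, "func")
    dir.create(sd, showWarnings = FALSE, recursive = TRUE)
    write_series(ph$series, file.path(sd, sprintf("%s_task-rest_bold.nii.gz", id)))
    for (n in seq_along(ph$truth_masks))
      write_mask(ph$truth_masks[[n]],
                 file.path(sd, sprintf("%s_frame-%03d_mask.nii.gz", id, n - 1)))
    utils::write.csv(ph$truth_motion, file.path(sd, sprintf("%s_motion.csv", id)),
                     row.names = FALSE)
  }
  manifest <- lapply(dataset$specs, function(s) unclass(s)[
    c("pseudo_age_weeks", "noise_sd", "ghost_fraction", "n_frames", "seed")])
  yaml::write_yaml(list(subjects = manifest,
                        splits = lapply(dataset$splits, as.list)),
                   file.path(dir, "manifest.yaml"))
  invisible(dir)
}
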