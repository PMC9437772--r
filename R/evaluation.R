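#' Voxelwise confusion counts between two masks
#'
#' Exhaustive classification of every voxel: TP (both foreground),
#' FP (predicted only), FN (reference only), TN (neither). Counts always
#' sum to the grid size.
#'
#' @param pred,ref binary masks (`volume3d` or 3D arrays) on one grid.
#' @return one-row tibble with columns `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(pred, ref) {
  p <- if (inherits(pred, "volume3d")) pred$data else pred
  r <- if (inherits(ref, "volume3d")) ref$data else ref
  if (inherits(pred, "volume3d") && inherits(ref, "volume3d"))
    stop_if_grid_mismatch(pred, ref, "prediction and reference")
  if (!all(dim(p) == dim(r))) stop("grid mismatch: mask shapes differ")
  tp <- sum(p * r)
  tibble::tibble(tp = tp, fp = sum(p) - tp, fn = sum(r) - tp,
                 tn = length(p) - sum(p) - sum(r) + tp)
}

# Surface voxels: foreground voxels with at least one six-connected
# background neighbour (volume faces count as background).
surface_voxels <- function(mask) {
  d <- dim(mask)
  fg <- mask != 0
  shift <- function(ax, by) {
    out <- array(FALSE, d)
    if (ax == 1) { if (by == 1) out[2:d[1], , ] <- fg[1:(d[1] - 1), , ] else out[1:(d[1] - 1), , ] <- fg[2:d[1], , ] }
    if (ax == 2) { if (by == 1) out[, 2:d[2], ] <- fg[, 1:(d[2] - 1), ] else out[, 1:(d[2] - 1), ] <- fg[, 2:d[2], ] }
    if (ax == 3) { if (by == 1) out[, , 2:d[3]] <- fg[, , 1:(d[3] - 1)] else out[, , 1:(d[3] - 1)] <- fg[, , 2:d[3]] }
    out
  }
  all_nb <- shift(1, 1) & shift(1, -1) & shift(2, 1) & shift(2, -1) &
            shift(3, 1) & shift(3, -1)
  which(fg & !all_nb, arr.ind = TRUE)
}

#' Symmetric Hausdorff surface distance in mm
#'
#' The maximum over both directed max-min Euclidean distances between the
#' foreground surface voxel sets (surface = foreground voxel with a
#' six-connected background neighbour), scaled by the anisotropic voxel
#' spacing. `percentile < 1` gives the percentile variant of the directed
#' distances instead of the maximum.
#'
#' @param pred,ref binary masks on one grid.
#' @param spacing voxel spacing in mm.
#' @param percentile quantile of the directed distances (default 1 = max).
#' @export
hausdorff_distance <- function(pred, ref, spacing = c(1, 1, 1), percentile = 1) {
  p <- if (inherits(pred, "volume3d")) pred$data else pred
  r <- if (inherits(ref, "volume3d")) ref$data else ref
  d <- dim(p)
  if (sum(p) == 0 && sum(r) == 0) return(0)
  if (sum(p) == 0 || sum(r) == 0) # undefined: report the grid diagonal
    return(sqrt(sum(((d - 1) * spacing)^2)))
  A <- sweep(surface_voxels(p) - 1, 2, spacing, "*")
  B <- sweep(surface_voxels(r) - 1, 2, spacing, "*")
  if (percentile >= 1) return(max(cpp_directed_maxmin(A, B), cpp_directed_maxmin(B, A)))
  dab <- apply(A, 1, function(a) sqrt(min(colSums((t(B) - a)^2))))
  dba <- apply(B, 1, function(b) sqrt(min(colSums((t(A) - b)^2))))
  max(stats::quantile(dab, percentile, names = FALSE),
      stats::quantile(dba, percentile, names = FALSE))
}

#' Segmentation agreement metrics
#'
#' Dice `2TP/(2TP+FP+FN)`, Jaccard `TP/(TP+FP+FN)`, symmetric Hausdorff
#' surface distance (mm), sensitivity `TP/(TP+FN)` and specificity
#' `TN/(TN+FP)`. Dice and Jaccard obey `J = D / (2 - D)` exactly.
#' Conventions for degenerate inputs: two empty masks are identical
#' (D = J = 1, H = 0); exactly one empty mask gives D = J = 0 and H equal
#' to the grid diagonal. Both paths emit a message.
#'
#' @param pred,ref binary masks on one grid.
#' @param spacing voxel spacing in mm (taken from `ref` if it is a
#'   `volume3d` and `spacing` is NULL).
#' @param volume_id,subject identifiers carried into the output row.
#' @return one-row tibble: subject, volume_id, dice, jaccard,
#'   hausdorff_mm, sensitivity, specificity.
#' @export
compute_metrics <- function(pred, ref, spacing = NULL,
                            volume_id = NA_character_, subject = NA_character_) {
  if (is.null(spacing))
    spacing <- if (inherits(ref, "volume3d")) ref$spacing else c(1, 1, 1)
  cc <- confusion(pred, ref)
  p_empty <- cc$tp + cc$fp == 0
  r_empty <- cc$tp + cc$fn == 0
  if (p_empty && r_empty) {
    message("both masks empty: Dice and Jaccard reported as 1, Hausdorff as 0")
    dice <- 1; jac <- 1; sens <- 1
  } else if (p_empty || r_empty) {
    message("one mask empty: Dice and Jaccard are 0; Hausdorff reported as the grid diagonal")
    dice <- 0; jac <- 0
    sens <- if (r_empty) 1 else 0
  } else {
    dice <- 2 * cc$tp / (2 * cc$tp + cc$fp + cc$fn)
    jac <- cc$tp / (cc$tp + cc$fp + cc$fn)
    sens <- cc$tp / (cc$tp + cc$fn)
  }
  spec <- if (cc$tn + cc$fp == 0) 1 else cc$tn / (cc$tn + cc$fp)
  tibble::tibble(subject = as.character(subject),
                 volume_id = as.character(volume_id),
                 dice = dice, jaccard = jac,
                 hausdorff_mm = hausdorff_distance(pred, ref, spacing),
                 sensitivity = sens, specificity = spec)
}

#' Aggregate per-volume metrics by subject
#'
#' Per-volume metric rows are averaged (unweighted) within each subject;
#' the grand per-volume mean across all rows is also returned, since test
#' performance is reported per volume but inspected per subject.
#'
#' @param metrics tibble of [compute_metrics()] rows with a `subject`
#'   column.
#' @return list with `by_subject` (one row per subject) and `per_volume`
#'   (one-row grand mean over all volumes).
#' @export
aggregate_by_subject <- function(metrics) {
  num <- c("dice", "jaccard", "hausdorff_mm", "sensitivity", "specificity")
  num <- intersect(num, names(metrics))
  list(
    by_subject = metrics |>
      dplyr::group_by(.data$subject) |>
      dplyr::summarise(dplyr::across(dplyr::all_of(num), mean),
                       n_volumes = dplyr::n(), .groups = "drop"),
    per_volume = metrics |>
      dplyr::summarise(dplyr::across(dplyr::all_of(num), mean),
                       n_volumes = dplyr::n())
  )
}

#' Flag volumes with low Dice for visual inspection
#'
#' Volumes whose Dice falls below the threshold (default 0.9) are the ones
#' worth visual QC; failures cluster around aliasing artifact and brains
#' far from the image origin.
#'
#' @param metrics tibble of per-volume metric rows.
#' @param threshold Dice below which a volume is flagged.
#' @return tibble of flagged rows, ordered by subject then Dice.
#' @export
flag_low_dice <- function(metrics, threshold = 0.9) {
  metrics |>
    dplyr::filter(.data$dice < threshold) |>
    dplyr::arrange(.data$subject, .data$dice)
}

#' Evaluate directories of predicted vs reference masks
#'
#' Pairs files by name between two directories, computes per-volume
#' metrics (spacing from each reference header) and optionally writes a
#' CSV. Subject ids are taken as the part of the filename before the
#' first underscore.
#'
#' @param pred_dir,ref_dir directories of NIFTI masks with matching names.
#' @param out_csv optional path for the metrics table.
#' @export
evaluate_mask_dirs <- function(pred_dir, ref_dir, out_csv = NULL) {
  files <- sort(list.files(ref_dir, pattern = "\\.nii(\\.gz)?$"))
  rows <- lapply(files, function(f) {
    pf <- file.path(pred_dir, f)
    if (!file.exists(pf)) stop(sprintf("missing predicted mask: %s", pf))
    ref <- read_volume(file.path(ref_dir, f))
    pred <- read_volume(pf)
    compute_metrics(pred, ref, volume_id = f,
                    subject = sub("_.*$", "", sub("\\.nii(\\.gz)?$", "", f)))
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  out
}
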