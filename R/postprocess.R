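#' Post-processing configuration
#'
#' @param threshold probability threshold (0 < threshold < 1, default 0.5,
#'   the softmax argmax equivalence point).
#' @param connectivity 3D neighbourhood used for clustering: 6, 18 or 26.
#' @export
postprocess_config <- function(threshold = 0.5, connectivity = 26) {
  stopifnot(threshold > 0, threshold < 1, connectivity %in% c(6, 18, 26))
  structure(list(threshold = threshold, connectivity = as.integer(connectivity),
                 component_policy = "keep-largest"),
            class = "postprocess_config")
}

#' Binarize a probability map into a brain mask
#'
#' Voxels at or above the threshold form candidates; candidates are
#' labelled into connected components (26-connectivity by default) and
#' only the largest is kept, discarding small non-brain clusters. There is
#' exactly one fetal brain per image, hence keep-largest rather than a
#' minimum-size filter. If no voxel reaches the threshold, an empty mask
#' is returned with a warning.
#'
#' @param prob a [volume3d()] with values in `[0, 1]` (a probability mask).
#' @param cfg a [postprocess_config()].
#' @return binary `volume3d` whose foreground is one connected component
#'   (or empty, on the warning path). Ties between equally largest
#'   components keep the first in column-major order.
#' @export
binarize_mask <- function(prob, cfg = postprocess_config()) {
  stopifnot(inherits(prob, "volume3d"))
  if (min(prob$data) < 0 || max(prob$data) > 1)
    stop("probability mask values must lie in [0, 1]")
  cand <- (prob$data >= cfg$threshold) * 1
  if (sum(cand) == 0) {
    warning("no voxel reached the probability threshold; returning an empty mask")
    prob$data <- cand
    return(prob)
  }
  lab <- cpp_label_components(cand, dim(cand), cfg$connectivity)
  sizes <- tabulate(lab)
  keep <- which.max(sizes)
  prob$data <- (lab == keep) * 1
  prob
}

#' Apply a binary mask to an image by voxelwise multiplication
#'
#' Outside-mask voxels become exactly 0; inside voxels are unchanged.
#'
#' @param vol image `volume3d` (native space).
#' @param mask binary `volume3d` on the same grid.
#' @export
apply_mask <- function(vol, mask) {
  stop_if_grid_mismatch(vol, mask, "image and mask")
  stopifnot(all(mask$data %in% c(0, 1)))
  vol$data <- vol$data * mask$data
  vol
}

#' Mask every frame of a series
#'
#' @param series a [time_series4d()].
#' @param masks list of binary `volume3d`, one per frame, or a single mask
#'   reused for all frames.
#' @export
apply_mask_series <- function(series, masks) {
  if (inherits(masks, "volume3d")) masks <- rep(list(masks), n_frames(series))
  stopifnot(length(masks) == n_frames(series))
  for (i in seq_len(n_frames(series)))
    series$data[, , , i] <- series$data[, , , i] * masks[[i]]$data
  series
}
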