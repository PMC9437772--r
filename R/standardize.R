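#' Network grid specification
#'
#' The masking network operates on a fixed grid: 3 mm isotropic voxels,
#' 96 x 96 in-plane, 37 axial slices. Every input volume is resampled and
#' symmetrically zero-padded onto this grid before prediction, and
#' predicted masks are carried back through the inverse mapping. The
#' in-plane shape must be divisible by `2^depth` of the network (96 allows
#' up to depth 5).
#'
#' @param target_shape integer length-3 grid shape.
#' @param target_spacing numeric length-3, mm (a scalar is recycled).
#' @export
grid_spec <- function(target_shape = c(96, 96, 37), target_spacing = c(3, 3, 3)) {
  target_shape <- as.integer(target_shape)
  target_spacing <- rep_len(as.numeric(target_spacing), 3)
  stopifnot(length(target_shape) == 3, all(target_shape > 0), all(target_spacing > 0))
  structure(list(target_shape = target_shape, target_spacing = target_spacing),
            class = "grid_spec")
}

# Mapping between a source grid and the standard grid. Standard voxel i
# maps to source voxel s = (i - ct) * f + cs (per axis, 0-based), where
# f = target_spacing / source_spacing, and ct/cs are the grid centres:
# resampling is symmetric about the volume centre, so padding is symmetric
# with ties toward the low index.
std_mapping <- function(source_dim, source_spacing, grid) {
  f <- grid$target_spacing / source_spacing
  ct <- (grid$target_shape - 1) / 2
  cs <- (source_dim - 1) / 2
  scaled <- round(source_dim * source_spacing / grid$target_spacing)
  list(f = f, ct = ct, cs = cs,
       pad_offsets = as.integer(floor((grid$target_shape - scaled) / 2)),
       crop_flags = source_dim * source_spacing >
         grid$target_shape * grid$target_spacing + 1e-9)
}

map_matrix <- function(m) { # standard voxel -> source voxel, 4x4
  M <- diag(c(m$f, 1))
  M[1:3, 4] <- m$cs - m$f * m$ct
  M
}

#' Standardize a volume onto the network grid
#'
#' Resamples (trilinear) onto the target spacing and zero-pads or
#' centre-crops symmetrically to the target shape, optionally followed by
#' robust intensity normalization. Everything needed to invert the mapping
#' is captured in the returned record.
#'
#' @param vol a [volume3d()].
#' @param grid a [grid_spec()].
#' @param normalize apply [normalize_intensity()] to the result.
#' @return list with elements `volume` (standardized [volume3d()]) and
#'   `record` (a `standardization_record`).
#' @export
standardize_volume <- function(vol, grid = grid_spec(), normalize = TRUE) {
  stopifnot(inherits(vol, "volume3d"), inherits(grid, "grid_spec"))
  m <- std_mapping(dim(vol$data), vol$spacing, grid)
  if (any(m$crop_flags))
    warning(sprintf("source extent exceeds the standard grid along axis %s; centre-cropping",
                    paste(which(m$crop_flags), collapse = ",")))
  V <- map_matrix(m)
  data <- cpp_resample3d(vol$data, dim(vol$data), grid$target_shape, V, 1L, 0)
  affine <- vol$affine %*% V
  out <- volume3d(data, grid$target_spacing, affine, frame_index = vol$frame_index)
  record <- structure(
    list(source_shape = dim(vol$data), source_spacing = vol$spacing,
         source_affine = vol$affine, grid = grid,
         resample_factors = m$f, pad_offsets = m$pad_offsets,
         crop_flags = m$crop_flags, intensity_scale = c(shift = 0, scale = 1)),
    class = "standardization_record"
  )
  if (normalize) {
    nz <- normalize_intensity(out)
    out <- nz$volume
    record$intensity_scale <- nz$intensity_scale
  }
  list(volume = out, record = record)
}

#' Robust intensity normalization to [0, 1]
#'
#' Shifts and scales by the 1st/99th intensity percentiles and clips, so
#' EPI intensity outliers do not compress the useful range. The transform
#' is order-preserving (weakly monotone; the clipped tails become ties).
#' A constant image maps to all zeros.
#'
#' @param vol a [volume3d()].
#' @param probs lower/upper percentiles used for scaling.
#' @return list with `volume` and the applied `intensity_scale`
#'   (`shift`, `scale`: `out = clip((in - shift) / scale, 0, 1)`).
#' @export
normalize_intensity <- function(vol, probs = c(0.01, 0.99)) {
  x <- vol$data
  if (any(!is.finite(x))) stop("volume contains non-finite values")
  q <- stats::quantile(x, probs, names = FALSE, type = 7)
  if (q[2] <= q[1]) {
    vol$data <- array(0, dim(x))
    return(list(volume = vol, intensity_scale = c(shift = q[1], scale = 1)))
  }
  vol$data <- array(pmin(1, pmax(0, (x - q[1]) / (q[2] - q[1]))), dim(x))
  list(volume = vol, intensity_scale = c(shift = q[1], scale = q[2] - q[1]))
}

#' Standardize a binary mask onto the network grid
#'
#' Same geometric mapping as [standardize_volume()] but with
#' nearest-neighbour interpolation so values stay binary; used to bring
#' reference masks onto the grid for training and standard-space scoring.
#'
#' @inheritParams standardize_volume
#' @param mask a binary [volume3d()].
#' @return a binary `volume3d` on the standard grid.
#' @export
standardize_mask <- function(mask, grid = grid_spec()) {
  stopifnot(inherits(mask, "volume3d"), all(mask$data %in% c(0, 1)))
  m <- std_mapping(dim(mask$data), mask$spacing, grid)
  V <- map_matrix(m)
  data <- cpp_resample3d(mask$data, dim(mask$data), grid$target_shape, V, 0L, 0)
  volume3d(data, grid$target_spacing, mask$affine %*% V,
           frame_index = mask$frame_index)
}

#' Carry a standard-grid mask back to native space
#'
#' Inverts the geometric part of [standardize_volume()] with
#' nearest-neighbour interpolation, so mask values stay binary. Margins
#' that were centre-cropped away (record `crop_flags`) come back as zeros.
#'
#' @param mask a binary `volume3d` on the standard grid.
#' @param record the `standardization_record` from the matching
#'   [standardize_volume()] call.
#' @return a binary `volume3d` on the source grid.
#' @export
invert_standardization <- function(mask, record) {
  stopifnot(inherits(record, "standardization_record"))
  grid <- record$grid
  if (!all(dim(mask$data) == grid$target_shape))
    stop("mask shape does not match the record's standard grid")
  m <- std_mapping(record$source_shape, record$source_spacing, grid)
  Minv <- solve(map_matrix(m)) # source voxel -> standard voxel
  data <- cpp_resample3d(mask$data, dim(mask$data), record$source_shape, Minv, 0L, 0)
  volume3d(data, record$source_spacing, record$source_affine,
           frame_index = mask$frame_index)
}
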