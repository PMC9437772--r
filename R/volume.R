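#' 3D volume and 4D time-series containers
#'
#' `volume3d()` wraps a 3D voxel grid together with its voxel spacing (mm)
#' and a 4x4 voxel-to-world affine (RAS+, 0-based voxel indices).
#' `time_series4d()` holds an ordered stack of grid-compatible frames as a
#' 4D array plus the repetition time. These two objects are the currency of
#' every stage of the pipeline.
#'
#' @param data 3D numeric array.
#' @param spacing numeric length-3, mm per voxel, strictly positive.
#' @param affine 4x4 voxel-to-world matrix; its upper-left 3x3 column norms
#'   must agree with `spacing`. Defaults to a spacing-scaled identity
#'   centred on the volume.
#' @param frame_index optional 0-based frame index.
#' @return An object of class `volume3d`.
#' @export
volume3d <- function(data, spacing = c(1, 1, 1), affine = NULL, frame_index = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive values (mm/voxel)")
  if (is.null(affine)) affine <- centered_affine(dim(data), spacing)
  affine <- unname(as.matrix(affine))
  stopifnot(all(dim(affine) == c(4, 4)))
  cn <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(abs(cn - spacing) > 1e-6 * pmax(1, spacing)))
    stop("affine column norms are inconsistent with spacing")
  structure(
    list(data = data, spacing = spacing, affine = affine, frame_index = frame_index),
    class = "volume3d"
  )
}

#' @rdname volume3d
#' @param frames 4D numeric array `[x, y, z, t]` or a list of `volume3d`
#'   sharing one grid.
#' @param tr_seconds repetition time in seconds (default 2, the usual fetal
#'   EPI protocol).
#' @export
time_series4d <- function(frames, spacing = c(1, 1, 1), affine = NULL, tr_seconds = 2) {
  if (is.list(frames)) return(merge_volumes(frames, tr_seconds = tr_seconds))
  stopifnot(is.array(frames), length(dim(frames)) == 4)
  proto <- volume3d(array(0, dim(frames)[1:3]), spacing, affine)
  structure(
    list(data = frames, spacing = proto$spacing, affine = proto$affine,
         tr_seconds = as.numeric(tr_seconds)),
    class = "time_series4d"
  )
}

#' @export
print.volume3d <- function(x, ...) {
  cat(sprintf("<volume3d> %s voxels @ %s mm%s\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              if (!is.null(x$frame_index)) sprintf(" [frame %d]", x$frame_index) else ""))
  invisible(x)
}

#' @export
print.time_series4d <- function(x, ...) {
  cat(sprintf("<time_series4d> %s voxels @ %s mm, %d frames, TR %.3g s\n",
              paste(dim(x$data)[1:3], collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              dim(x$data)[4], x$tr_seconds))
  invisible(x)
}

#' @export
dim.volume3d <- function(x) dim(x$data)

#' @export
dim.time_series4d <- function(x) dim(x$data)

#' Number of frames in a series
#' @param series a `time_series4d`.
#' @export
n_frames <- function(series) dim(series$data)[4]

#' Extract one frame of a series as a `volume3d`
#' @param series a `time_series4d`.
#' @param i 1-based frame position; the returned `frame_index` is `i - 1`.
#' @export
get_frame <- function(series, i) {
  stopifnot(i >= 1, i <= n_frames(series))
  volume3d(series$data[, , , i, drop = TRUE], series$spacing, series$affine,
           frame_index = i - 1L)
}

# Default affine: axes aligned with voxel axes, world origin at the volume
# centre (keeps phantoms and templates centred at 0 mm).
centered_affine <- function(dim3, spacing) {
  a <- diag(c(spacing, 1))
  a[1:3, 4] <- -(dim3 - 1) / 2 * spacing
  a
}

same_grid <- function(a, b, tol = 1e-6) {
  all(dim(a$data)[1:3] == dim(b$data)[1:3]) &&
    max(abs(a$spacing - b$spacing)) <= tol &&
    max(abs(a$affine - b$affine)) <= tol
}

stop_if_grid_mismatch <- function(a, b, what = "volumes") {
  if (!same_grid(a, b))
    stop(sprintf("grid mismatch: %s differ in shape, spacing or affine", what))
  invisible(TRUE)
}

# Smoothed 2x-decimated copy, used as the coarse level of registration.
half_volume <- function(v) {
  sm <- cpp_gauss_smooth3d(v$data, dim(v$data), rep(0.85, 3))
  d <- dim(v$data)
  idx <- lapply(d, function(n) seq(1, n, by = 2))
  aff <- v$affine
  aff[1:3, 1:3] <- aff[1:3, 1:3] * 2
  volume3d(sm[idx[[1]], idx[[2]], idx[[3]]], v$spacing * 2, aff)
}

#' Resample a volume onto an arbitrary grid
#'
#' Pulls values from `vol` onto the grid described by `target_dim` /
#' `target_affine`: output voxel v reads the source at
#' `solve(vol$affine) %*% world %*% target_affine %*% v`.
#'
#' @param vol source `volume3d`.
#' @param target_dim integer length-3 output grid shape.
#' @param target_affine 4x4 voxel-to-world affine of the output grid.
#' @param world optional extra 4x4 world-to-world transform (defaults to
#'   identity): a point p on the target grid samples the source at world
#'   position `world %*% p`.
#' @param method `"linear"` (images), `"nearest"` (masks) or `"cubic"`
#'   (Keys tricubic; sharper, used where interpolation bias matters).
#' @param cval fill value outside the source grid.
#' @return numeric 3D array of shape `target_dim`.
#' @export
resample_volume <- function(vol, target_dim, target_affine, world = NULL,
                            method = c("linear", "nearest", "cubic"), cval = 0) {
  method <- match.arg(method)
  M <- solve(vol$affine)
  if (!is.null(world)) M <- M %*% world
  M <- M %*% target_affine
  code <- c(nearest = 0L, linear = 1L, cubic = 2L)[[method]]
  cpp_resample3d(vol$data, dim(vol$data), as.integer(target_dim), M, code, cval)
}
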