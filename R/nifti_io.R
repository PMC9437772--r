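#' Read a NIFTI-1 file as a 4D time series
#'
#' A 3D file is returned as a one-frame series. Spacing and the
#' voxel-to-world affine come from the header (sform preferred); the
#' repetition time is read from `pixdim[4]` and falls back to 2 s when the
#' header leaves it unset, matching the usual fetal EPI protocol.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return a [time_series4d()].
#' @export
read_series <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  nd <- length(dim(img))
  if (nd < 3 || nd > 4)
    stop(sprintf("expected a 3D or 4D NIFTI, got %dD (%s)", nd, path))
  pd <- RNifti::pixdim(img)
  spacing <- abs(pd[1:3])
  tr <- if (nd == 4 && length(pd) >= 4 && is.finite(pd[4]) && pd[4] > 0) pd[4] else 2
  arr <- array(as.numeric(img), if (nd == 3) c(dim(img), 1) else dim(img))
  aff <- unname(structure(RNifti::xform(img), imagedim = NULL, code = NULL))
  time_series4d(arr, spacing = spacing, affine = matrix(aff, 4, 4), tr_seconds = tr)
}

#' Read a NIFTI-1 file as a single 3D volume
#'
#' Errors if the file holds more than one frame.
#' @inheritParams read_series
#' @return a [volume3d()].
#' @export
read_volume <- function(path) {
  s <- read_series(path)
  if (n_frames(s) != 1)
    stop(sprintf("expected a single 3D volume, got %d frames", n_frames(s)))
  get_frame(s, 1)
}

#' Split a 4D series into per-timepoint 3D volumes
#'
#' The masking network consumes individual timepoints, so series are split
#' into 3D volumes and later merged back. `merge_volumes(split_series(s))`
#' reproduces `s` bit-exactly.
#'
#' @param series a [time_series4d()].
#' @return list of [volume3d()], in frame order.
#' @export
split_series <- function(series) {
  stopifnot(inherits(series, "time_series4d"))
  lapply(seq_len(n_frames(series)), function(i) get_frame(series, i))
}

#' Merge grid-compatible 3D volumes into a 4D series
#'
#' @param frames list of [volume3d()] sharing one grid.
#' @param tr_seconds repetition time of the merged series.
#' @return a [time_series4d()].
#' @export
merge_volumes <- function(frames, tr_seconds = 2) {
  stopifnot(is.list(frames), length(frames) >= 1)
  ref <- frames[[1]]
  for (f in frames[-1]) stop_if_grid_mismatch(ref, f, "frames to merge")
  arr <- array(0, c(dim(ref$data), length(frames)))
  for (i in seq_along(frames)) arr[, , , i] <- frames[[i]]$data
  time_series4d(arr, ref$spacing, ref$affine, tr_seconds = tr_seconds)
}

as_nifti_image <- function(data, spacing, affine, datatype, tr = NULL) {
  attr(data, "pixdim") <- if (is.null(tr)) spacing else c(spacing, tr)
  img <- RNifti::asNifti(data, datatype = datatype, internal = FALSE)
  RNifti::sform(img) <- structure(affine, code = 2L)
  img
}

#' Write volumes and series to NIFTI-1
#'
#' Images are stored as 32-bit float; binary masks as unsigned 8-bit
#' (pass `datatype = "uint8"` or use [write_mask()]).
#'
#' @param series a [time_series4d()].
#' @param vol a [volume3d()].
#' @param path destination `.nii` / `.nii.gz`.
#' @param datatype NIFTI on-disk datatype.
#' @return the path, invisibly.
#' @export
write_series <- function(series, path, datatype = "float") {
  stopifnot(inherits(series, "time_series4d"))
  img <- as_nifti_image(series$data, series$spacing, series$affine, datatype,
                        tr = series$tr_seconds)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_series
#' @export
write_volume <- function(vol, path, datatype = "float") {
  stopifnot(inherits(vol, "volume3d"))
  img <- as_nifti_image(vol$data, vol$spacing, vol$affine, datatype)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_series
#' @param mask a binary `volume3d` (values 0/1).
#' @export
write_mask <- function(mask, path) {
  stopifnot(all(mask$data %in% c(0, 1)))
  write_volume(mask, path, datatype = "uint8")
}
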