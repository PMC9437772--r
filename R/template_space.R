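#' Affine (12-DOF) registration to a template
#'
#' Estimates translation, rotation, scale and shear mapping the template
#' grid onto the moving volume, maximizing normalized cross-correlation.
#' The search is initialized from the 6-DOF rigid solution, then all 12
#' parameters are refined (coarse-to-fine, Nelder-Mead). Both volumes
#' should be brain-only (masked) or both whole.
#'
#' @param mean_vol moving `volume3d` (typically the mean realigned frame).
#' @param template target `volume3d`.
#' @param smooth_vox pre-smoothing sigma in voxels (see [register_rigid()]).
#' @return an `affine_transform`: list with `matrix` (4x4 world map),
#'   `parameters` (12), `center`, `ncc`.
#' @export
register_affine <- function(mean_vol, template, smooth_vox = 1) {
  if (stats::sd(mean_vol$data) == 0 || stats::sd(template$data) == 0)
    stop("degenerate (constant) image; cannot register")
  rig <- register_rigid(mean_vol, template, smooth_vox = smooth_vox)
  center <- attr(rig, "center")
  if (smooth_vox > 0) {
    mean_vol$data <- cpp_gauss_smooth3d(mean_vol$data, dim(mean_vol$data),
                                        rep(smooth_vox, 3))
    template$data <- cpp_gauss_smooth3d(template$data, dim(template$data),
                                        rep(smooth_vox, 3))
  }
  p0 <- c(as.numeric(rig), 1, 1, 1, 0, 0, 0)
  parscale <- c(1, 1, 1, 0.02, 0.02, 0.02, 0.05, 0.05, 0.05, 0.02, 0.02, 0.02)
  obj_factory <- function(tpl, mov) {
    rv <- as.vector(tpl$data); rv <- rv - mean(rv)
    rn <- sqrt(sum(rv^2))
    function(p) {
      M <- affine_params_matrix(p, center)
      s <- resample_volume(mov, dim(tpl$data), tpl$affine, world = M)
      sv <- as.vector(s) - mean(s)
      den <- rn * sqrt(sum(sv^2))
      if (den == 0) return(1)
      1 - sum(rv * sv) / den
    }
  }
  # coarse level (restarted Nelder-Mead escapes simplex collapse in 12-D),
  # then a full-resolution polish
  obj_c <- obj_factory(half_volume(template), half_volume(mean_vol))
  fit <- stats::optim(p0, obj_c, method = "Nelder-Mead",
                      control = list(parscale = parscale, maxit = 2000, reltol = 1e-12))
  fit <- stats::optim(fit$par, obj_c, method = "Nelder-Mead",
                      control = list(parscale = parscale, maxit = 2000, reltol = 1e-12))
  obj_f <- obj_factory(template, mean_vol)
  fit <- stats::optim(fit$par, obj_f, method = "Nelder-Mead",
                      control = list(parscale = parscale, maxit = 800, reltol = 1e-12))
  fit <- stats::optim(fit$par, obj_f, method = "Nelder-Mead",
                      control = list(parscale = parscale, maxit = 800, reltol = 1e-12))
  structure(list(matrix = affine_params_matrix(fit$par, center),
                 parameters = stats::setNames(fit$par,
                   c("tx", "ty", "tz", "rx", "ry", "rz",
                     "sx", "sy", "sz", "hxy", "hxz", "hyz")),
                 center = center, ncc = 1 - fit$value),
            class = "affine_transform")
}

#' @export
print.affine_transform <- function(x, ...) {
  cat(sprintf("<affine_transform> scale (%.3f, %.3f, %.3f), NCC %.4f\n",
              x$parameters["sx"], x$parameters["sy"], x$parameters["sz"], x$ncc))
  invisible(x)
}

#' Warp a series onto a template grid
#'
#' Every frame is resampled onto the template grid through the transform's
#' world map (trilinear for images, nearest-neighbour for masks).
#'
#' @param series a [time_series4d()].
#' @param transform an `affine_transform` (or a plain 4x4 world matrix).
#' @param template `volume3d` defining the target grid.
#' @param method interpolation, `"linear"` or `"nearest"`.
#' @export
warp_series <- function(series, transform, template, method = c("linear", "nearest")) {
  method <- match.arg(method)
  M <- if (inherits(transform, "affine_transform")) transform$matrix else transform
  nf <- n_frames(series)
  arr <- array(0, c(dim(template$data), nf))
  for (i in seq_len(nf))
    arr[, , , i] <- resample_volume(get_frame(series, i), dim(template$data),
                                    template$affine, world = M, method = method)
  time_series4d(arr, template$spacing, template$affine, tr_seconds = series$tr_seconds)
}

#' Gaussian spatial smoothing
#'
#' Per-frame 3D Gaussian smoothing with a kernel of the requested
#' full-width-at-half-maximum: `sigma = fwhm / (2 sqrt(2 ln 2))` per axis,
#' converted to voxels through the spacing. Boundaries are zero-padded
#' without renormalization, consistent with masked (background-zero)
#' data; `fwhm_mm = 0` is the identity.
#'
#' @param series a [time_series4d()] (or a `volume3d`).
#' @param fwhm_mm kernel FWHM in mm (>= 0).
#' @export
smooth_series <- function(series, fwhm_mm = 4) {
  if (fwhm_mm < 0) stop("fwhm_mm must be non-negative")
  if (fwhm_mm == 0) return(series)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / series$spacing
  if (inherits(series, "volume3d")) {
    series$data <- cpp_gauss_smooth3d(series$data, dim(series$data), sigma_vox)
    return(series)
  }
  for (i in seq_len(n_frames(series)))
    series$data[, , , i] <- cpp_gauss_smooth3d(series$data[, , , i],
                                               dim(series$data)[1:3], sigma_vox)
  series
}

#' Save / load a transform as a 4x4 text matrix
#' @param transform `affine_transform` or 4x4 matrix.
#' @param path destination text file (4 rows of 4 numbers).
#' @export
write_transform <- function(transform, path) {
  M <- if (inherits(transform, "affine_transform")) transform$matrix else transform
  utils::write.table(format(M, digits = 12), path,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  as.matrix(utils::read.table(path))[1:4, 1:4, drop = FALSE] |> unname()
}
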