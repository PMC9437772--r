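#' Rigid-body transforms
#'
#' A rigid transform is parameterized by three translations (mm) and three
#' rotations (radians) about the world x, y, z axes, applied in the order
#' x, y, z about a fixed centre of rotation (normally the volume centre in
#' world coordinates): `T(p) = R (p - c) + c + t` with `R = Rz Ry Rx`.
#'
#' @param tx,ty,tz translations in mm.
#' @param rx,ry,rz rotations in radians.
#' @return `rigid_transform` object (named numeric of length 6).
#' @export
rigid_transform <- function(tx = 0, ty = 0, tz = 0, rx = 0, ry = 0, rz = 0) {
  structure(c(tx = tx, ty = ty, tz = tz, rx = rx, ry = ry, rz = rz),
            class = "rigid_transform")
}

rot3 <- function(rx, ry, rz) {
  cx <- cos(rx); sx <- sin(rx); cy <- cos(ry); sy <- sin(ry); cz <- cos(rz); sz <- sin(rz)
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

#' Convert rigid parameters to a 4x4 world-to-world matrix
#' @param t a `rigid_transform` (or numeric length 6).
#' @param center centre of rotation, world mm (default origin).
#' @export
rigid_matrix <- function(t, center = c(0, 0, 0)) {
  t <- as.numeric(t)
  R <- rot3(t[4], t[5], t[6])
  M <- diag(4)
  M[1:3, 1:3] <- R
  M[1:3, 4] <- t[1:3] + center - R %*% center
  M
}

#' Recover rigid parameters from a 4x4 rigid matrix
#'
#' Inverse of [rigid_matrix()] for the same Euler convention
#' (`R = Rz(rz) Ry(ry) Rx(rx)`); `ry` is taken in `[-pi/2, pi/2]`.
#' @param M 4x4 rigid matrix.
#' @param center centre of rotation used when building `M`.
#' @export
rigid_parameters <- function(M, center = c(0, 0, 0)) {
  R <- M[1:3, 1:3]
  ry <- asin(max(-1, min(1, -R[3, 1])))
  if (abs(cos(ry)) > 1e-9) {
    rx <- atan2(R[3, 2], R[3, 3])
    rz <- atan2(R[2, 1], R[1, 1])
  } else { # gimbal lock: fold rz into rx
    rx <- atan2(-R[2, 3], R[2, 2])
    rz <- 0
  }
  tr <- M[1:3, 4] - center + R %*% center
  rigid_transform(tr[1], tr[2], tr[3], rx, ry, rz)
}

#' Compose and invert rigid transforms
#'
#' Composition follows matrix order: `compose_rigid(a, b)` applies `b`
#' first, then `a`.
#' @param a,b,t `rigid_transform` objects.
#' @param center shared centre of rotation, world mm.
#' @export
compose_rigid <- function(a, b, center = c(0, 0, 0)) {
  rigid_parameters(rigid_matrix(a, center) %*% rigid_matrix(b, center), center)
}

#' @rdname compose_rigid
#' @export
invert_rigid <- function(t, center = c(0, 0, 0)) {
  rigid_parameters(solve(rigid_matrix(t, center)), center)
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid> t = (%.3f, %.3f, %.3f) mm, r = (%.3f, %.3f, %.3f) deg\n",
              x[1], x[2], x[3], x[4] * 180 / pi, x[5] * 180 / pi, x[6] * 180 / pi))
  invisible(x)
}

# 12-parameter affine: translations, rotations, scales, shears;
# A = T R Sh Sc about `center`. Used by template-space registration.
affine_params_matrix <- function(p, center = c(0, 0, 0)) {
  R <- rot3(p[4], p[5], p[6])
  Sc <- diag(p[7:9])
  Sh <- diag(3); Sh[1, 2] <- p[10]; Sh[1, 3] <- p[11]; Sh[2, 3] <- p[12]
  A3 <- R %*% Sh %*% Sc
  M <- diag(4)
  M[1:3, 1:3] <- A3
  M[1:3, 4] <- p[1:3] + center - A3 %*% center
  M
}

world_center <- function(vol) {
  c(vol$affine %*% c((dim(vol$data) - 1) / 2, 1))[1:3]
}
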