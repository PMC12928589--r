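#' Proper rigid transform
#'
#' Carrier for every pose change in the package: a proper rotation matrix
#' plus a translation (mm), acting as `x -> R x + t`. The constructor
#' enforces orthonormality and `det = +1` to 1e-9.
#'
#' @param rotation 3x3 proper orthonormal matrix.
#' @param translation numeric length-3 (mm).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3L, 3L)) || length(translation) != 3L)
    stop("rigid_transform needs a 3x3 rotation and a length-3 translation")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9)
    stop("rotation must be proper orthonormal (det +1) to 1e-9")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- tryCatch(.rotation_angle_deg(x$rotation), error = function(e) NA)
  cat(sprintf("rigid_transform: rotation %.4f deg, translation (%.4f, %.4f, %.4f) mm\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Apply a rigid transform to a point matrix
#'
#' @param transform a [rigid_transform()].
#' @param points n x 3 numeric matrix (mm).
#' @return n x 3 matrix of transformed points.
#' @export
transform_points <- function(transform, points) {
  points <- as.matrix(points)
  sweep(points %*% t(transform$rotation), 2, -transform$translation)
}

#' Compose two rigid transforms
#'
#' `compose_transforms(a, b)` returns the transform that applies `b` first,
#' then `a` (i.e. `a %after% b`).
#'
#' @param a,b [rigid_transform()] objects.
#' @return a [rigid_transform()].
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#'
#' @param transform a [rigid_transform()].
#' @return the inverse [rigid_transform()].
#' @export
invert_transform <- function(transform) {
  rt <- t(transform$rotation)
  rigid_transform(rt, -as.numeric(rt %*% transform$translation))
}

# Rodrigues rotation matrix about unit direction u (radians).
.rodrigues <- function(u, theta) {
  u <- u / sqrt(sum(u^2))
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

.rotation_angle_deg <- function(R) {
  s <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  atan2(sqrt(sum(s^2)) / 2, (sum(diag(R)) - 1) / 2) * 180 / pi
}

#' Rotation about an axis line
#'
#' Builds the rigid transform rotating by `angle` degrees about the line of
#' an axis. Every point of the line is a fixed point (zero pitch); the sign
#' follows the right-hand rule about the axis direction.
#'
#' @param axis an [axis_line()].
#' @param angle rotation angle in degrees (signed).
#' @return a [rigid_transform()].
#' @export
rotation_about_axis <- function(axis, angle) {
  stopifnot(is.finite(angle))
  R <- .rodrigues(axis$direction, angle * pi / 180)
  p <- axis$start
  rigid_transform(R, p - as.numeric(R %*% p))
}

#' Best-fit rigid transform between corresponded point sets
#'
#' Closed-form least-squares superposition (SVD/Kabsch): the rigid transform
#' minimising the sum of squared index-paired vertex distances from `source`
#' to `target`. Used as the stage-1 initializer of the axis fit and as a
#' test oracle.
#'
#' @param source,target corresponded [tri_mesh()] objects.
#' @return a [rigid_transform()] with attribute `residual_rms` (mm).
#' @export
best_fit_rigid <- function(source, target) {
  stopifnot_corresponded(source, target)
  X <- source$vertices; Y <- target$vertices
  cx <- colMeans(X); cy <- colMeans(Y)
  H <- crossprod(sweep(X, 2, cx), sweep(Y, 2, cy))
  sv <- svd(H)
  if (sv$d[2] <= 1e-12 * max(sv$d[1], 1))
    stop("degenerate (rank-deficient) vertex configuration; cannot fit a rigid transform")
  S <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  R <- sv$v %*% S %*% t(sv$u)
  t <- cy - as.numeric(R %*% cx)
  out <- rigid_transform(R, t)
  d <- transform_points(out, X) - Y
  attr(out, "residual_rms") <- sqrt(mean(rowSums(d^2)))
  out
}

#' Screw decomposition of a rigid transform
#'
#' Decomposes a rigid transform into a rotation by `angle` degrees about a
#' line (`axis_point`, `axis_direction`) plus a `pitch` translation along
#' that line (Chasles' theorem). Recomposition reproduces the input to
#' 1e-9. Transforms whose rotation angle falls below `min_angle` have no
#' usable screw axis (the instantaneous centre of rotation is numerically
#' meaningless) and are rejected.
#'
#' @param transform a [rigid_transform()].
#' @param min_angle smallest usable rotation angle in degrees (default 0.05).
#' @return An object of class `screw_decomposition`: fields `axis_point`,
#'   `axis_direction` (unit), `angle` (degrees, in (0, 180]), `pitch` (mm).
#' @export
screw_decompose <- function(transform, min_angle = 0.05) {
  R <- transform$rotation; tv <- transform$translation
  s <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  sin_t <- sqrt(sum(s^2)) / 2
  cos_t <- (sum(diag(R)) - 1) / 2
  theta <- atan2(sin_t, cos_t)
  if (theta * 180 / pi < min_angle)
    stop(sprintf("degenerate rotation: axis undefined below min_angle = %g deg", min_angle))
  if (sin_t > 1e-8) {
    u <- s / (2 * sin_t)
  } else {
    # angle ~ 180 deg: axis from the +1 eigenvector of R
    ev <- eigen(R)
    k <- which.min(abs(ev$values - 1))
    u <- Re(ev$vectors[, k])
    u <- u / sqrt(sum(u^2))
  }
  pitch <- sum(tv * u)
  t_perp <- tv - pitch * u
  # (I - R) has null space span(u); adding u u^T makes the system regular
  # and forces the solution into the plane through the origin normal to u.
  p <- solve(diag(3) - R + tcrossprod(u), t_perp)
  structure(list(axis_point = as.numeric(p), axis_direction = as.numeric(u),
                 angle = theta * 180 / pi, pitch = pitch),
            class = "screw_decomposition")
}

#' Recompose a screw decomposition into a rigid transform
#'
#' @param screw a `screw_decomposition`.
#' @return a [rigid_transform()]: rotation about the screw line followed by
#'   the pitch translation along it.
#' @export
screw_recompose <- function(screw) {
  R <- .rodrigues(screw$axis_direction, screw$angle * pi / 180)
  p <- screw$axis_point
  tv <- p - as.numeric(R %*% p) + screw$pitch * screw$axis_direction
  rigid_transform(R, tv)
}

#' @export
print.screw_decomposition <- function(x, ...) {
  cat(sprintf("screw: angle %.4f deg, pitch %.4f mm, axis (%.3f, %.3f, %.3f) + t(%.3f, %.3f, %.3f)\n",
              x$angle, x$pitch, x$axis_point[1], x$axis_point[2], x$axis_point[3],
              x$axis_direction[1], x$axis_direction[2], x$axis_direction[3]))
  invisible(x)
}
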