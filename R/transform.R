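#' Rigid transforms
#'
#' A rigid transform maps points as `p -> R p + t` with `R` a proper rotation
#' (orthonormal, det +1) and `t` a translation in mm. Transforms compose and
#' invert within the type.
#'
#' @param rotation 3x3 proper rotation matrix.
#' @param translation numeric 3-vector (mm).
#' @return An object of class `rigid_transform` with fields `rotation` and
#'   `translation`.
#' @examples
#' tr <- rigid_transform(diag(3), c(1, 0, 0))
#' compose_transform(tr, invert_transform(tr))
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  R <- as.matrix(rotation)
  t <- as.numeric(translation)
  if (!all(dim(R) == c(3, 3)) || length(t) != 3) {
    stop("rotation must be 3x3 and translation length 3", call. = FALSE)
  }
  stopifnot_finite(R, "rotation"); stopifnot_finite(t, "translation")
  if (max(abs(crossprod(R) - diag(3))) > 1e-9) {
    stop("rotation is not orthonormal within 1e-9", call. = FALSE)
  }
  if (abs(det(R) - 1) > 1e-9) {
    stop("rotation determinant is not +1 (improper rotation/reflection)", call. = FALSE)
  }
  structure(list(rotation = R, translation = t), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle_deg(x$rotation)
  cat(sprintf("<rigid_transform: rotation %.3f deg, translation (%.3f, %.3f, %.3f) mm>\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' @rdname rigid_transform
#' @param a,b rigid transforms; `compose_transform(a, b)` applies `b` first.
#' @export
compose_transform <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' @rdname rigid_transform
#' @param transform a rigid transform.
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(Rt, -as.numeric(Rt %*% transform$translation))
}

#' Apply a rigid transform to points
#'
#' Maps every point `p -> R p + t`; the cloud label is preserved.
#'
#' @param cloud a [point_cloud()] or plain `n x 3` matrix.
#' @param transform a [rigid_transform()].
#' @return Object of the same kind as `cloud`.
#' @export
apply_transform <- function(cloud, transform) {
  m <- if (inherits(cloud, "point_cloud")) as_cloud_matrix(cloud) else as.matrix(cloud)
  out <- m %*% t(transform$rotation)
  out <- sweep(out, 2, transform$translation, "+")
  if (inherits(cloud, "point_cloud")) point_cloud(out, label = cloud_label(cloud)) else out
}

#' @rdname apply_transform
#' @export
apply_registration <- apply_transform

# Rotation magnitude in degrees (used in reporting/tests).
rotation_angle_deg <- function(R) {
  c_ <- (sum(diag(R)) - 1) / 2
  rad2deg(acos(max(-1, min(1, c_))))
}

# Elementary rotations (radians), internal.
rot_x <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), 3, 3)
}
rot_y <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, 0, -sa, 0, 1, 0, sa, 0, ca), 3, 3)
}
rot_z <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
}

# Rotation about an arbitrary unit axis (Rodrigues), internal.
rot_axis_angle <- function(axis, angle_rad) {
  u <- unitize(axis, "rotation axis")
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle_rad) * K + (1 - cos(angle_rad)) * (K %*% K)
}

#' Serialise a rigid transform to JSON
#'
#' The JSON stores the rotation row-major (`rotation` as 9 numbers) plus the
#' translation, so transforms interchange with other tools.
#'
#' @param transform a [rigid_transform()].
#' @param path output path.
#' @export
write_transform <- function(transform, path) {
  jsonlite::write_json(
    list(rotation = as.numeric(t(transform$rotation)),
         translation = transform$translation),
    path, digits = 12, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(matrix(as.numeric(x$rotation), 3, 3, byrow = TRUE),
                  as.numeric(x$translation))
}
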