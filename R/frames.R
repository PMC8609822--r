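#' Anatomical coordinate frames
#'
#' A frame is an origin plus a right-handed orthonormal triad stored as the
#' columns (x, y, z) of a 3x3 matrix expressed in world coordinates. For the
#' pelvis, X points anteriorly, Y superiorly and Z laterally toward the
#' subject's right; the femur frame uses the analogous lowercase convention
#' (x anterior, y superior along the mechanical axis, z lateral).
#'
#' @param origin numeric 3-vector (mm).
#' @param axes 3x3 matrix whose columns are the x, y, z unit vectors.
#' @param body `"pelvis"` or `"femur"`.
#' @return An object of class `anatomical_frame`.
#' @export
anatomical_frame <- function(origin, axes, body = c("pelvis", "femur")) {
  body <- match.arg(body)
  axes <- as.matrix(axes)
  if (!all(dim(axes) == c(3, 3))) stop("axes must be 3x3", call. = FALSE)
  if (max(abs(crossprod(axes) - diag(3))) > 1e-9) {
    stop("frame axes are not orthonormal within 1e-9", call. = FALSE)
  }
  if (max(abs(cross3(axes[, 1], axes[, 2]) - axes[, 3])) > 1e-9) {
    stop("frame is not right-handed (x cross y must equal z)", call. = FALSE)
  }
  colnames(axes) <- c("x", "y", "z")
  structure(list(origin = as.numeric(origin), axes = axes, body = body),
            class = "anatomical_frame")
}

#' @export
print.anatomical_frame <- function(x, ...) {
  cat(sprintf("<%s frame at (%.2f, %.2f, %.2f) mm>\n",
              x$body, x$origin[1], x$origin[2], x$origin[3]))
  print(round(x$axes, 4))
  invisible(x)
}

check_landmarks <- function(landmarks, needed) {
  missing <- setdiff(needed, names(landmarks))
  if (length(missing)) {
    stop("missing landmarks: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  lapply(landmarks[needed], function(v) {
    v <- as.numeric(v)
    if (length(v) != 3 || !all(is.finite(v))) {
      stop("landmarks must be finite 3-vectors", call. = FALSE)
    }
    v
  })
}

#' Build the ISB pelvis frame
#'
#' Z is the unit vector from left to right ASIS (pointing toward the
#' subject's right); X lies in the plane of the two ASIS and the PSIS
#' midpoint, perpendicular to Z, pointing anteriorly (from the PSIS midpoint
#' toward the ASIS midpoint); Y = Z x X points superiorly by construction of
#' the right-handed triad. The origin is the acetabulum centre (centre of the
#' sphere fitted to the lunate surface).
#'
#' @param landmarks named list containing `RASIS`, `LASIS`, `RPSIS`, `LPSIS`
#'   and `acetabulum_center` (3-vectors, mm).
#' @return An [anatomical_frame()] with `body = "pelvis"`.
#' @export
build_pelvis_frame <- function(landmarks) {
  lm <- check_landmarks(landmarks,
                        c("RASIS", "LASIS", "RPSIS", "LPSIS", "acetabulum_center"))
  asis_vec <- lm$RASIS - lm$LASIS
  if (vnorm(asis_vec) < 1e-9) {
    stop("degenerate frame: RASIS and LASIS coincide", call. = FALSE)
  }
  Z <- asis_vec / vnorm(asis_vec)
  psis_mid <- (lm$RPSIS + lm$LPSIS) / 2
  asis_mid <- (lm$RASIS + lm$LASIS) / 2
  ant <- asis_mid - psis_mid
  ant_in <- ant - sum(ant * Z) * Z
  if (vnorm(ant_in) < 1e-9) {
    stop("degenerate frame: ASIS and PSIS landmarks are collinear", call. = FALSE)
  }
  X <- ant_in / vnorm(ant_in)
  Y <- cross3(Z, X)
  anatomical_frame(lm$acetabulum_center, cbind(X, Y, Z), body = "pelvis")
}

#' Build the ISB femur frame
#'
#' y is the unit vector from the epicondyle midpoint to the femoral head
#' centre (pointing superiorly); z lies in the plane of the head centre and
#' the two epicondyles, perpendicular to y, pointing laterally (from the
#' medial toward the lateral epicondyle); x = y x z points anteriorly and
#' completes the right-handed triad. The origin is the head centre.
#'
#' @param landmarks named list containing `medial_epicondyle` and
#'   `lateral_epicondyle`.
#' @param head_fit a [fit_sphere()] result for the femoral head (or a list
#'   with a `center` field).
#' @return An [anatomical_frame()] with `body = "femur"`.
#' @export
build_femur_frame <- function(landmarks, head_fit) {
  lm <- check_landmarks(landmarks, c("medial_epicondyle", "lateral_epicondyle"))
  head <- as.numeric(head_fit$center)
  epi_mid <- (lm$medial_epicondyle + lm$lateral_epicondyle) / 2
  if (vnorm(lm$lateral_epicondyle - lm$medial_epicondyle) < 1e-9) {
    stop("degenerate frame: epicondyles coincide", call. = FALSE)
  }
  yv <- head - epi_mid
  if (vnorm(yv) < 1e-9) {
    stop("degenerate frame: head centre lies at the epicondyle midpoint", call. = FALSE)
  }
  y <- yv / vnorm(yv)
  lat <- lm$lateral_epicondyle - lm$medial_epicondyle
  lat_in <- lat - sum(lat * y) * y
  if (vnorm(lat_in) < 1e-9) {
    stop("degenerate frame: head centre lies on the epicondyle line", call. = FALSE)
  }
  z <- lat_in / vnorm(lat_in)
  x <- cross3(y, z)
  anatomical_frame(head, cbind(x, y, z), body = "femur")
}

#' Hip joint angle triples
#'
#' Container for (flexion, adduction, internal rotation) in degrees with the
#' clinical sign convention: positive flexion, positive adduction, positive
#' internal rotation on both sides.
#'
#' @param flexion,adduction,internal_rotation angles in degrees, each in
#'   (-180, 180].
#' @param side `"right"` or `"left"`.
#' @return An object of class `hip_angles` (named numeric vector with a
#'   `side` attribute).
#' @export
hip_angles <- function(flexion, adduction, internal_rotation,
                       side = c("right", "left")) {
  side <- match.arg(side)
  v <- c(flexion = as.numeric(flexion), adduction = as.numeric(adduction),
         internal_rotation = as.numeric(internal_rotation))
  stopifnot_finite(v, "hip angles")
  if (any(v <= -180 | v > 180)) stop("angles must lie in (-180, 180]", call. = FALSE)
  structure(v, side = side, class = "hip_angles")
}

#' @export
print.hip_angles <- function(x, ...) {
  cat(sprintf("<hip_angles (%s): flexion %.1f, adduction %.1f, internal rotation %.1f deg>\n",
              attr(x, "side"), x[["flexion"]], x[["adduction"]],
              x[["internal_rotation"]]))
  invisible(x)
}

# Mirror the femur frame across the pelvis mid-sagittal plane (normal =
# pelvis Z) so a left hip can be decomposed with the right-side formulas.
# Reflection flips handedness; re-negating the mirrored x axis restores a
# right-handed triad representing the equivalent right femur.
mirror_femur_frame <- function(femur, pelvis_Z) {
  M <- diag(3) - 2 * tcrossprod(pelvis_Z)
  ax <- femur$axes
  anatomical_frame(femur$origin,
                   cbind(-as.numeric(M %*% ax[, 1]),
                         as.numeric(M %*% ax[, 2]),
                         as.numeric(M %*% ax[, 3])),
                   body = "femur")
}

#' Grood-Suntay hip angles from anatomical frames
#'
#' Decomposes the orientation of the femur frame relative to the pelvis frame
#' using the joint coordinate system with e1 = pelvis Z (body-fixed flexion
#' axis), e2 = femur y (body-fixed internal/external rotation axis) and the
#' floating axis e3 = e1 x e2 (ab/adduction). Extraction uses atan2-based
#' direction cosines. For left hips the femur frame is mirrored across the
#' pelvis mid-sagittal plane first, so positive flexion/adduction/internal
#' rotation mean the same clinically on both sides.
#'
#' When the flexion and rotation axes approach alignment (adduction near
#' +/-90 deg, `|e1 . e2| > 0.999`) the result carries a `gimbal` attribute
#' set to `TRUE`; angles are still returned.
#'
#' @param pelvis,femur [anatomical_frame()]s.
#' @param side `"right"` or `"left"`.
#' @return A [hip_angles()] object (attribute `gimbal` flags near-singular
#'   configurations).
#' @export
grood_suntay_angles <- function(pelvis, femur, side = c("right", "left")) {
  side <- match.arg(side)
  if (side == "left") femur <- mirror_femur_frame(femur, pelvis$axes[, 3])
  R <- crossprod(pelvis$axes, femur$axes)  # femur axes in pelvis coordinates
  # R = Rz(flexion) Rx(adduction) Ry(internal rotation) for the right side
  s_add <- R[3, 2]                         # = pelvis Z . femur y
  gimbal <- abs(s_add) > 0.999
  adduction <- asin(max(-1, min(1, s_add)))
  flexion <- atan2(-R[1, 2], R[2, 2])
  rotation <- atan2(-R[3, 1], R[3, 3])
  out <- hip_angles(rad2deg(flexion), rad2deg(adduction), rad2deg(rotation),
                    side = side)
  attr(out, "gimbal") <- gimbal
  if (gimbal) {
    warning("hip angles near gimbal singularity (|e1.e2| > 0.999); ",
            "adduction is close to +/-90 deg", call. = FALSE)
  }
  out
}

#' Compose a femur frame from hip angles (forward construction)
#'
#' Inverse of [grood_suntay_angles()]: given a pelvis frame and a clinical
#' angle triple, returns the femur frame that decomposes back to exactly
#' those angles. Used by the motion simulator and for round-trip testing.
#'
#' @param pelvis an [anatomical_frame()].
#' @param angles a [hip_angles()] object (its `side` attribute is used).
#' @param origin origin for the femur frame (default: pelvis origin).
#' @return An [anatomical_frame()] with `body = "femur"`.
#' @export
compose_hip_angles <- function(pelvis, angles, origin = NULL) {
  side <- attr(angles, "side")
  R_rel <- rot_z(deg2rad(angles[["flexion"]])) %*%
    rot_x(deg2rad(angles[["adduction"]])) %*%
    rot_y(deg2rad(angles[["internal_rotation"]]))
  axes <- pelvis$axes %*% R_rel
  fr <- anatomical_frame(if (is.null(origin)) pelvis$origin else origin,
                         axes, body = "femur")
  if (identical(side, "left")) fr <- mirror_femur_frame(fr, pelvis$axes[, 3])
  fr
}

#' Rigidly move an anatomical frame
#'
#' Maps the origin by `p -> R p + t` and the axes by `R`; orthonormality is
#' preserved exactly.
#'
#' @param frame an [anatomical_frame()].
#' @param transform a [rigid_transform()].
#' @return The moved [anatomical_frame()].
#' @export
frame_pose <- function(frame, transform) {
  anatomical_frame(
    as.numeric(transform$rotation %*% frame$origin) + transform$translation,
    transform$rotation %*% frame$axes,
    body = frame$body)
}
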