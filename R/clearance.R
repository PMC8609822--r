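#' Alpha plane from head fit and femoral axes
#'
#' The alpha plane passes through the femoral head centre, contains the neck
#' axis direction, and has normal `unit(neck x shaft)`; it is the oblique
#' plane on which alpha/beta angles are measured. The neck and shaft axes
#' must be separated by more than `min_angle` degrees.
#'
#' @param head_fit a [fit_sphere()] result for the femoral head.
#' @param neck_axis,shaft_axis [hip_axis()] objects.
#' @param min_angle minimum neck/shaft separation in degrees (default 5).
#' @return A [hip_plane()] through the head centre.
#' @export
build_alpha_plane <- function(head_fit, neck_axis, shaft_axis, min_angle = 5) {
  n <- neck_axis$direction; s <- shaft_axis$direction
  sep <- rad2deg(asin(min(1, vnorm(cross3(n, s)))))
  if (sep < min_angle) {
    stop(sprintf(
      "degenerate plane: neck and shaft axes are near-parallel (%.2f deg < %.0f deg)",
      sep, min_angle), call. = FALSE)
  }
  hip_plane(head_fit$center, cross3(n, s))
}

#' Stack of planes parallel to the alpha plane
#'
#' Planes at offsets `k * spacing` along the base-plane normal for
#' `k = -count_each_side, ..., +count_each_side`, replicating a stack of
#' parallel image slices (default spacing 2.5 mm, slab half-thickness
#' 0.5 mm).
#'
#' @param base a [hip_plane()] (typically from [build_alpha_plane()]).
#' @param spacing plane spacing in mm (> 0).
#' @param count_each_side number of planes on each side of the base plane.
#' @param half_thickness slab half-thickness used when slicing (> 0 and at
#'   most `spacing / 2` so slabs do not overlap).
#' @return An object of class `alpha_plane_stack`: list with `base`,
#'   `spacing`, `half_thickness`, `offsets` and `planes`.
#' @export
build_plane_stack <- function(base, spacing = 2.5, count_each_side = 5L,
                              half_thickness = 0.5) {
  if (spacing <= 0) stop("spacing must be > 0", call. = FALSE)
  if (half_thickness <= 0) stop("half_thickness must be > 0", call. = FALSE)
  if (half_thickness > spacing / 2) {
    stop("half_thickness must be <= spacing / 2 (non-overlapping slabs)", call. = FALSE)
  }
  count_each_side <- as.integer(count_each_side)
  if (count_each_side < 0) stop("count_each_side must be >= 0", call. = FALSE)
  offsets <- seq(-count_each_side, count_each_side) * spacing
  planes <- lapply(offsets, function(o) hip_plane(base$point + o * base$normal, base$normal))
  structure(list(base = base, spacing = spacing, half_thickness = half_thickness,
                 offsets = offsets, planes = planes),
            class = "alpha_plane_stack")
}

#' @export
print.alpha_plane_stack <- function(x, ...) {
  cat(sprintf("<alpha_plane_stack: %d planes, spacing %.2f mm, slab +/-%.2f mm>\n",
              length(x$planes), x$spacing, x$half_thickness))
  invisible(x)
}

#' Extract the planar section of the hip at one slice
#'
#' Slices the femur and acetabulum clouds with a closed slab around `plane`
#' and projects the kept points (and the head centre) into one shared
#' orthonormal in-plane basis: `u` is the in-plane projection of the neck
#' direction (pointing from the head centre toward the neck), `v = n x u`
#' with the sign of `v` chosen so that `direction_hint` (when given) has a
#' positive `v` component. Angular coordinates around the projected head
#' centre are measured from `u` toward `v` in degrees.
#'
#' The section's `head_radius` is the radius of the head sphere's circle in
#' this plane (`sqrt(r^2 - h^2)` for plane offset `h` from the centre). A
#' section is flagged unusable when the plane misses the head sphere, has
#' fewer than `min_femur` femur points or `min_acetabulum` acetabular points,
#' or when the slab's own projection spread on the head sphere exceeds
#' `tolerance`: within a slab of half-thickness `w`, on-sphere points project
#' up to `sqrt(r^2 - (|h| - w)^2) - sqrt(r^2 - h^2)` outside the slice
#' circle, and once this exceeds the asphericity tolerance a spherical
#' contour is no longer distinguishable from an aspherical one (near-tangent
#' slices).
#'
#' @param femur,acetabulum [point_cloud()]s in the same (posed) frame.
#' @param plane a [hip_plane()].
#' @param half_thickness slab half-thickness in mm.
#' @param head_fit [fit_sphere()] result for the femoral head (posed frame).
#' @param neck_direction 3-vector: femoral neck direction, head centre toward
#'   neck (posed frame).
#' @param direction_hint optional 3-vector selecting the marching side
#'   (anterior); default keeps `v = n x u`.
#' @param tolerance asphericity tolerance (mm) used for the projection-spread
#'   usability check (match the tolerance passed to
#'   [find_asphericity_onset()]).
#' @param min_femur,min_acetabulum usability thresholds on point counts.
#' @return An object of class `section_contour`: `plane_index` (filled by
#'   [min_beta()]), `femur_2d`, `acetabulum_2d` (centred on the projected
#'   head centre), `femur_angle`, `femur_radius`, `acetabulum_angle` (deg),
#'   `head_radius`, `usable`, `reason`, plus the projection basis.
#' @export
extract_section <- function(femur, acetabulum, plane, half_thickness, head_fit,
                            neck_direction, direction_hint = NULL,
                            tolerance = 0.5, min_femur = 10L,
                            min_acetabulum = 3L) {
  u_in <- neck_direction - sum(neck_direction * plane$normal) * plane$normal
  if (vnorm(u_in) < 1e-9) {
    stop("neck direction is parallel to the plane normal", call. = FALSE)
  }
  u <- u_in / vnorm(u_in)
  v <- cross3(plane$normal, u)
  if (!is.null(direction_hint)) {
    hv <- sum(direction_hint * v)
    if (abs(hv) > 1e-12 && hv < 0) v <- -v
  }
  h <- sum((head_fit$center - plane$point) * plane$normal)
  slice_r2 <- head_fit$radius^2 - h^2
  fem <- slice_by_plane(femur, plane, half_thickness)
  ace <- slice_by_plane(acetabulum, plane, half_thickness)
  center2d <- project_point_uv(head_fit$center, plane, u, v)
  f2 <- sweep(project_points_uv(fem, plane, u, v), 2, center2d, "-")
  a2 <- sweep(project_points_uv(ace, plane, u, v), 2, center2d, "-")
  usable <- TRUE; reason <- ""
  if (slice_r2 <= 0) {
    usable <- FALSE; reason <- "plane misses the femoral head sphere"
  } else {
    inner <- max(abs(h) - half_thickness, 0)
    spread <- sqrt(max(head_fit$radius^2 - inner^2, 0)) - sqrt(slice_r2)
    if (spread > tolerance) {
      usable <- FALSE
      reason <- "slab projection spread on the head sphere exceeds the asphericity tolerance (near-tangent slice)"
    }
  }
  if (nrow(f2) < min_femur) { usable <- FALSE; reason <- paste0(reason, if (nzchar(reason)) "; ", "too few femur points") }
  if (nrow(a2) < min_acetabulum) { usable <- FALSE; reason <- paste0(reason, if (nzchar(reason)) "; ", "too few acetabular points") }
  structure(list(
    plane_index = NA_integer_,
    femur_2d = f2, acetabulum_2d = a2,
    femur_radius = sqrt(rowSums(f2^2)),
    femur_angle = wrap180(rad2deg(atan2(f2[, 2], f2[, 1]))),
    acetabulum_angle = wrap180(rad2deg(atan2(a2[, 2], a2[, 1]))),
    head_center_2d = c(0, 0),
    head_radius = if (slice_r2 > 0) sqrt(slice_r2) else NA_real_,
    plane = plane, u = u, v = v,
    usable = usable, reason = reason),
    class = "section_contour")
}

project_points_uv <- function(cloud, plane, u, v) {
  m <- if (inherits(cloud, "point_cloud")) as_cloud_matrix(cloud) else as.matrix(cloud)
  d <- sweep(m, 2, plane$point, "-")
  cbind(as.numeric(d %*% u), as.numeric(d %*% v))
}

project_point_uv <- function(p, plane, u, v) {
  d <- as.numeric(p) - plane$point
  c(sum(d * u), sum(d * v))
}

#' @export
print.section_contour <- function(x, ...) {
  cat(sprintf("<section_contour: %d femur / %d acetabulum points, head radius %s mm%s>\n",
              nrow(x$femur_2d), nrow(x$acetabulum_2d),
              if (is.na(x$head_radius)) "NA" else sprintf("%.2f", x$head_radius),
              if (x$usable) "" else paste0(" [unusable: ", x$reason, "]")))
  invisible(x)
}

#' Locate the onset of head asphericity in a section
#'
#' Orders the femur contour points by decreasing angular coordinate (marching
#' from deep inside the acetabulum toward the neck on the marching side,
#' angles in `(0, 180]`) and returns the first point whose radial distance
#' from the head centre exceeds `head_radius + tolerance` and that begins a
#' run of at least `run_min` consecutive supra-threshold points (isolated
#' spikes are noise, not a cam). If no such run exists the contour is
#' spherical through the slab and a no-onset result is returned.
#'
#' @param section a [extract_section()] result (must be usable).
#' @param tolerance radial deviation above the fitted head radius that counts
#'   as aspherical (mm, default 0.5).
#' @param run_min noise-guard run length (default 3).
#' @return A list with `found` (flag), `point` (2D coords), `angle` (deg) and
#'   `index` into the section's femur points; `found = FALSE` if the contour
#'   stays on-sphere.
#' @export
find_asphericity_onset <- function(section, tolerance = 0.5, run_min = 3L) {
  if (!isTRUE(section$usable)) stop("section is not usable: ", section$reason, call. = FALSE)
  sel <- which(section$femur_angle > 0)
  if (!length(sel)) return(list(found = FALSE, point = NULL, angle = NA_real_, index = NA_integer_))
  ord <- sel[order(section$femur_angle[sel], decreasing = TRUE)]
  supra <- section$femur_radius[ord] > section$head_radius + tolerance
  n <- length(supra)
  if (n >= run_min) {
    # first index starting a run of >= run_min consecutive supra points
    run_ok <- supra
    for (k in seq_len(run_min - 1L)) {
      run_ok <- run_ok & c(supra[-seq_len(k)], rep(FALSE, k))
    }
    hit <- which(run_ok)
    if (length(hit)) {
      i <- ord[hit[1]]
      return(list(found = TRUE, point = section$femur_2d[i, ],
                  angle = section$femur_angle[i], index = i))
    }
  }
  list(found = FALSE, point = NULL, angle = NA_real_, index = NA_integer_)
}

#' Locate the acetabular rim point in a section
#'
#' The acetabular section is an arc around the head centre (it may wrap
#' across +/-180 deg when the cup covers the pole opposite the neck). The
#' rim point is the endpoint of that arc on the marching side: the largest
#' circular gap in the sorted acetabular angles separates the two arc
#' endpoints, and the endpoint bounding the gap from above (the first
#' acetabular point encountered when marching from deep inside the
#' acetabulum toward the neck in decreasing angle) is the rim. When no gap
#' of at least `min_gap` degrees exists the acetabulum covers the entire
#' slice circle and there is no rim margin in this plane (`found = FALSE`);
#' the plane is non-informative.
#'
#' @param section a usable [extract_section()] result.
#' @param min_gap smallest angular gap (deg) accepted as a genuine arc
#'   opening rather than sampling noise.
#' @return A list with `found`, `point` (2D), `angle` (deg, wrapped) and
#'   `index`.
#' @export
find_rim_point <- function(section, min_gap = 20) {
  if (!isTRUE(section$usable)) stop("section is not usable: ", section$reason, call. = FALSE)
  ang <- section$acetabulum_angle
  if (!length(ang)) {
    stop("empty acetabular contour; section unusable", call. = FALSE)
  }
  ord <- order(ang)
  a <- ang[ord]
  n <- length(a)
  gaps <- if (n == 1) 360 else c(a[-1] - a[-n], a[1] + 360 - a[n])
  j <- which.max(gaps)
  if (gaps[j] < min_gap) {
    return(list(found = FALSE, point = NULL, angle = NA_real_, index = NA_integer_))
  }
  i <- ord[if (j == n) 1L else j + 1L]
  list(found = TRUE, point = section$acetabulum_2d[i, ], angle = ang[i],
       index = i)
}

#' Beta angle within one section
#'
#' Signed angle at the head centre from the rim ray to the onset ray,
#' positive when the onset lies beyond the rim in the marching direction
#' (clearance between head-neck junction and rim), negative when the onset
#' lies under acetabular coverage (overlap/impingement). The ray ambiguity is
#' resolved to the range (-90, 270]: overlap deeper than 90 deg is
#' anatomically impossible (the neck would cross the acetabular wall), so a
#' nominal difference beyond that range is a rim far on the posterior side
#' of a degenerate slice and is kept as a large positive clearance instead
#' of a spurious deep-negative value.
#'
#' @param section a [extract_section()] result (supplies the head centre).
#' @param onset,rim 2D points (as returned by [find_asphericity_onset()] and
#'   [find_rim_point()], fields `point`), relative to the head centre.
#' @return Beta in degrees.
#' @export
beta_angle_in_plane <- function(section, onset, rim) {
  onset <- as.numeric(onset); rim <- as.numeric(rim)
  if (vnorm(onset) < 1e-9 || vnorm(rim) < 1e-9) {
    stop("degenerate ray: onset or rim coincides with the head centre", call. = FALSE)
  }
  a_onset <- rad2deg(atan2(onset[2], onset[1]))
  a_rim <- rad2deg(atan2(rim[2], rim[1]))
  ((a_rim - a_onset + 90) %% 360) - 90
}

#' Minimum beta angle over a plane stack
#'
#' Computes the beta angle in every usable plane of the stack and returns the
#' per-plane values together with the minimum. Planes flagged unusable (too
#' few points, plane misses the head) or with no asphericity onset are
#' excluded from the minimum and recorded.
#'
#' @param femur,acetabulum posed [point_cloud()]s.
#' @param stack an [build_plane_stack()] result.
#' @param head_fit [fit_sphere()] of the femoral head in the posed frame.
#' @param neck_direction posed neck direction (head centre toward neck).
#' @param tolerance asphericity tolerance in mm (see
#'   [find_asphericity_onset()]).
#' @param direction_hint optional marching-side hint (see
#'   [extract_section()]).
#' @return An object of class `beta_result`: `per_plane` (data frame with
#'   `plane_index`, `offset_mm`, `usable`, `beta_deg`, onset/rim angles),
#'   `min_beta` (deg), `min_plane_index`, `excluded` (reasons per excluded
#'   plane) and `settings`.
#' @export
min_beta <- function(femur, acetabulum, stack, head_fit, neck_direction,
                     tolerance = 0.5, direction_hint = NULL) {
  k <- seq_along(stack$planes)
  idx <- k - 1L - (length(k) - 1L) %/% 2L   # symmetric indices ... -1, 0, 1 ...
  rows <- vector("list", length(k))
  excluded <- character(0)
  for (i in k) {
    sec <- extract_section(femur, acetabulum, stack$planes[[i]],
                           stack$half_thickness, head_fit, neck_direction,
                           direction_hint = direction_hint,
                           tolerance = tolerance)
    sec$plane_index <- idx[i]
    if (!sec$usable) {
      rows[[i]] <- data.frame(plane_index = idx[i], offset_mm = stack$offsets[i],
                              usable = FALSE, beta_deg = NA_real_,
                              onset_angle = NA_real_, rim_angle = NA_real_)
      excluded <- c(excluded, sprintf("plane %d: %s", idx[i], sec$reason))
      next
    }
    onset <- find_asphericity_onset(sec, tolerance = tolerance)
    if (!onset$found) {
      rows[[i]] <- data.frame(plane_index = idx[i], offset_mm = stack$offsets[i],
                              usable = FALSE, beta_deg = NA_real_,
                              onset_angle = NA_real_, rim_angle = NA_real_)
      excluded <- c(excluded, sprintf("plane %d: no asphericity onset", idx[i]))
      next
    }
    rim <- find_rim_point(sec)
    if (!rim$found) {
      rows[[i]] <- data.frame(plane_index = idx[i], offset_mm = stack$offsets[i],
                              usable = FALSE, beta_deg = NA_real_,
                              onset_angle = NA_real_, rim_angle = NA_real_)
      excluded <- c(excluded,
                    sprintf("plane %d: acetabulum covers the slice circle (no rim margin)",
                            idx[i]))
      next
    }
    beta <- beta_angle_in_plane(sec, onset$point, rim$point)
    rows[[i]] <- data.frame(plane_index = idx[i], offset_mm = stack$offsets[i],
                            usable = TRUE, beta_deg = beta,
                            onset_angle = onset$angle, rim_angle = rim$angle)
  }
  per_plane <- do.call(rbind, rows)
  ok <- which(per_plane$usable)
  if (!length(ok)) {
    stop("no usable plane in the stack: ", paste(excluded, collapse = "; "),
         call. = FALSE)
  }
  imin <- ok[which.min(per_plane$beta_deg[ok])]
  structure(list(per_plane = per_plane,
                 min_beta = per_plane$beta_deg[imin],
                 min_plane_index = per_plane$plane_index[imin],
                 excluded = excluded,
                 settings = list(spacing = stack$spacing,
                                 half_thickness = stack$half_thickness,
                                 tolerance = tolerance)),
            class = "beta_result")
}

#' @export
print.beta_result <- function(x, ...) {
  n_ok <- sum(x$per_plane$usable)
  cat(sprintf("<beta_result: min beta %.2f deg at plane %d (%d/%d usable planes)>\n",
              x$min_beta, x$min_plane_index, n_ok, nrow(x$per_plane)))
  invisible(x)
}

#' Enforce the reference centre-to-centre distance
#'
#' Translates the femur along the line joining the femoral head centre and
#' the acetabulum centre so that the centre-to-centre distance equals the
#' reference distance measured on the supine scans; the rotation is
#' unchanged. When both the current and the reference distance are
#' (numerically) zero the clouds are already concentric and the femur is
#' returned unchanged; a zero current distance with a nonzero reference is an
#' error because the translation direction is undefined.
#'
#' @param femur posed femur [point_cloud()].
#' @param head_fit [fit_sphere()] of the posed femoral head.
#' @param acetabulum_center 3-vector (posed frame).
#' @param reference_distance target distance in mm (>= 0).
#' @return A list with the translated `femur`, updated `head_center`, and the
#'   `translation` applied.
#' @export
adjust_center_distance <- function(femur, head_fit, acetabulum_center,
                                   reference_distance) {
  d_vec <- as.numeric(acetabulum_center) - head_fit$center
  d <- vnorm(d_vec)
  if (d < 1e-9) {
    if (reference_distance < 1e-9) {
      return(list(femur = femur, head_center = head_fit$center,
                  translation = c(0, 0, 0)))
    }
    stop("undefined direction: head and acetabulum centres coincide but a ",
         "nonzero reference distance was requested", call. = FALSE)
  }
  shift <- (d - reference_distance) * (d_vec / d)
  tr <- rigid_transform(diag(3), shift)
  list(femur = apply_transform(femur, tr),
       head_center = head_fit$center + shift,
       translation = shift)
}

#' Pose the bone models at a motion frame
#'
#' Applies the supine-to-frame pelvis transform to the acetabulum and the
#' supine-to-frame femur transform to the femur, then enforces the reference
#' centre-to-centre distance with [adjust_center_distance()].
#'
#' @param femur,acetabulum supine [point_cloud()]s.
#' @param supine_to_frame_femur,supine_to_frame_pelvis [rigid_transform()]s.
#' @param head_fit [fit_sphere()] of the supine femoral head.
#' @param acetabulum_center 3-vector, supine frame.
#' @param reference_distance target centre-to-centre distance (mm).
#' @return A list with posed `femur`, `acetabulum`, `head_center`,
#'   `acetabulum_center`.
#' @export
place_models_at_frame <- function(femur, acetabulum, supine_to_frame_femur,
                                  supine_to_frame_pelvis, head_fit,
                                  acetabulum_center, reference_distance) {
  fem <- apply_transform(femur, supine_to_frame_femur)
  ace <- apply_transform(acetabulum, supine_to_frame_pelvis)
  head_posed <- as.numeric(supine_to_frame_femur$rotation %*% head_fit$center) +
    supine_to_frame_femur$translation
  ace_posed <- as.numeric(supine_to_frame_pelvis$rotation %*% as.numeric(acetabulum_center)) +
    supine_to_frame_pelvis$translation
  adj <- adjust_center_distance(
    fem, list(center = head_posed, radius = head_fit$radius), ace_posed,
    reference_distance)
  list(femur = adj$femur, acetabulum = ace,
       head_center = adj$head_center, acetabulum_center = ace_posed)
}
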