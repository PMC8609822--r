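#' Fit a subject-specific hip clearance model
#'
#' Builds the subject-specific model that predicts anterior femoroacetabular
#' clearance (the beta angle): spheres are fitted to the femoral head and the
#' acetabular lunate surface, ISB pelvis and femur anatomical frames are
#' constructed from the landmarks, the alpha plane is derived from the neck
#' and shaft axes, and the supine centre-to-centre distance is recorded as
#' the reference distance.
#'
#' @param femur,acetabulum supine [point_cloud()]s of the bones.
#' @param landmarks named list with `RASIS`, `LASIS`, `RPSIS`, `LPSIS`,
#'   `medial_epicondyle`, `lateral_epicondyle` (3-vectors, mm).
#' @param neck_axis femoral neck axis: a [hip_axis()], or a [point_cloud()]
#'   of neck-surface points to fit (the direction is oriented from the head
#'   centre toward the neck).
#' @param head_points cloud of femoral-head articular points used for the
#'   head sphere fit; defaults to `femur` (adequate only if the head
#'   dominates the cloud — pass the segmented head surface when available).
#' @param shaft_axis femoral shaft axis: a [hip_axis()], a [point_cloud()]
#'   to fit, or `NULL` to use the mechanical axis (epicondyle midpoint to
#'   head centre).
#' @param side `"right"` or `"left"`.
#' @param spacing,half_thickness,tolerance clearance-model settings: plane
#'   spacing (mm), slab half-thickness (mm) and asphericity tolerance (mm).
#' @param count_each_side planes on each side of the alpha plane; default
#'   `ceiling(head_radius / spacing)` so the stack spans the head.
#' @return An object of class `hip_model`.
#' @seealso [predict.hip_model()], [min_beta()], [run_full_pipeline()]
#' @export
hip_model <- function(femur, acetabulum, landmarks, neck_axis,
                      head_points = NULL, shaft_axis = NULL,
                      side = c("right", "left"),
                      spacing = 2.5, half_thickness = 0.5, tolerance = 0.5,
                      count_each_side = NULL) {
  side <- match.arg(side)
  if (is.null(head_points)) head_points <- femur
  head_fit <- fit_sphere(head_points, exclude_above = tolerance)
  acet_fit <- fit_sphere(acetabulum)
  lm <- landmarks
  lm$femoral_head_center <- head_fit$center
  lm$acetabulum_center <- acet_fit$center
  pelvis_frame <- build_pelvis_frame(lm)
  femur_frame <- build_femur_frame(lm, head_fit)
  if (inherits(neck_axis, "point_cloud") || is.matrix(neck_axis)) {
    # the neck axis passes through the head centre; the centroid of the neck
    # surface lies on the axis, so the head-centre-to-centroid line recovers
    # the axis far more accurately than a principal-component fit on a short
    # cylinder (whose length/diameter ratio is close to 1 for femoral necks)
    centroid <- colMeans(as.matrix(neck_axis))
    neck_axis <- hip_axis(head_fit$center, centroid - head_fit$center)
  }
  # orient the neck direction away from the head centre
  to_neck <- neck_axis$point - head_fit$center
  if (vnorm(to_neck) > 1e-9 && sum(neck_axis$direction * to_neck) < 0) {
    neck_axis <- hip_axis(neck_axis$point, -neck_axis$direction)
  }
  if (is.null(shaft_axis)) {
    epi_mid <- (lm$medial_epicondyle + lm$lateral_epicondyle) / 2
    shaft_axis <- hip_axis(epi_mid, head_fit$center - epi_mid)
  } else if (inherits(shaft_axis, "point_cloud") || is.matrix(shaft_axis)) {
    shaft_axis <- fit_axis(shaft_axis, hint = c(0, 1, 0))
  }
  alpha <- build_alpha_plane(head_fit, neck_axis, shaft_axis)
  if (is.null(count_each_side)) count_each_side <- ceiling(head_fit$radius / spacing)
  structure(list(
    femur = femur, acetabulum = acetabulum,
    head_fit = head_fit, acetabulum_fit = acet_fit,
    landmarks = lm,
    pelvis_frame = pelvis_frame, femur_frame = femur_frame,
    neck_axis = neck_axis, shaft_axis = shaft_axis,
    alpha_plane = alpha,
    reference_distance = vnorm(head_fit$center - acet_fit$center),
    side = side,
    settings = list(spacing = spacing, half_thickness = half_thickness,
                    tolerance = tolerance, count_each_side = count_each_side)),
    class = "hip_model")
}

#' @export
print.hip_model <- function(x, ...) {
  cat("Subject-specific hip clearance model\n")
  cat(sprintf("  side: %s\n", x$side))
  cat(sprintf("  femoral head: radius %.2f mm (fit rms %.3f mm)\n",
              x$head_fit$radius, x$head_fit$rms_residual))
  cat(sprintf("  acetabulum:   radius %.2f mm (fit rms %.3f mm)\n",
              x$acetabulum_fit$radius, x$acetabulum_fit$rms_residual))
  cat(sprintf("  centre-to-centre reference distance: %.3f mm\n",
              x$reference_distance))
  cat(sprintf("  reslicing: %d planes, spacing %.2f mm, slab +/-%.2f mm, tolerance %.2f mm\n",
              2 * x$settings$count_each_side + 1, x$settings$spacing,
              x$settings$half_thickness, x$settings$tolerance))
  invisible(x)
}

#' @export
summary.hip_model <- function(object, ...) {
  neutral <- beta_at_pose(object)
  out <- list(model = object, neutral_beta = neutral)
  class(out) <- "summary.hip_model"
  out
}

#' @export
print.summary.hip_model <- function(x, ...) {
  print(x$model)
  cat(sprintf("  neutral-pose minimum beta: %.2f deg (plane %d)\n",
              x$neutral_beta$min_beta, x$neutral_beta$min_plane_index))
  invisible(x)
}

#' @export
coef.hip_model <- function(object, ...) {
  c(head_radius = object$head_fit$radius,
    acetabulum_radius = object$acetabulum_fit$radius,
    reference_distance = object$reference_distance)
}

#' Beta angle of the model at one rigid pose
#'
#' Poses the bone models with explicit supine-to-frame transforms (default
#' identity, the supine pose), enforces the reference centre-to-centre
#' distance and computes [min_beta()] over the model's plane stack.
#'
#' @param model a [hip_model()].
#' @param femur_transform,pelvis_transform [rigid_transform()]s.
#' @return A [min_beta()] `beta_result`.
#' @export
beta_at_pose <- function(model, femur_transform = rigid_transform(),
                         pelvis_transform = rigid_transform()) {
  placed <- place_models_at_frame(model$femur, model$acetabulum,
                                  femur_transform, pelvis_transform,
                                  model$head_fit, model$acetabulum_fit$center,
                                  model$reference_distance)
  head_posed <- list(center = placed$head_center, radius = model$head_fit$radius)
  neck_dir <- as.numeric(femur_transform$rotation %*% model$neck_axis$direction)
  shaft_dir <- as.numeric(femur_transform$rotation %*% model$shaft_axis$direction)
  alpha <- hip_plane(placed$head_center, cross3(neck_dir, shaft_dir))
  stack <- build_plane_stack(alpha, spacing = model$settings$spacing,
                             count_each_side = model$settings$count_each_side,
                             half_thickness = model$settings$half_thickness)
  min_beta(placed$femur, placed$acetabulum, stack, head_posed, neck_dir,
           tolerance = model$settings$tolerance)
}

#' Predict beta clearance from hip joint angles
#'
#' For each angle triple, composes the femur pose relative to the supine
#' pelvis (rotation about the femoral head centre), poses the models and
#' computes the minimum beta angle over the plane stack. The pelvis is held
#' in its supine pose; to drive both bodies from motion-capture transforms
#' use [beta_at_pose()] or [run_full_pipeline()].
#'
#' @param object a [hip_model()].
#' @param newdata data frame with columns `flexion`, `adduction`,
#'   `internal_rotation` (degrees), or a numeric triple.
#' @param ... unused.
#' @return A data frame with one row per input pose: the angles, `beta_min`,
#'   `min_plane_index` and `n_usable_planes`.
#' @export
predict.hip_model <- function(object, newdata, ...) {
  if (is.numeric(newdata)) {
    newdata <- data.frame(flexion = newdata[1], adduction = newdata[2],
                          internal_rotation = newdata[3])
  }
  need <- c("flexion", "adduction", "internal_rotation")
  if (!all(need %in% names(newdata))) {
    stop("newdata needs columns flexion, adduction, internal_rotation", call. = FALSE)
  }
  head <- object$head_fit$center
  out <- newdata[, need, drop = FALSE]
  out$beta_min <- NA_real_
  out$min_plane_index <- NA_integer_
  out$n_usable_planes <- NA_integer_
  for (i in seq_len(nrow(newdata))) {
    ang <- hip_angles(newdata$flexion[i], newdata$adduction[i],
                      newdata$internal_rotation[i], side = object$side)
    fr <- compose_hip_angles(object$pelvis_frame, ang, origin = head)
    Rw <- fr$axes %*% t(object$femur_frame$axes)
    tf <- rigid_transform(Rw, head - as.numeric(Rw %*% head))
    res <- tryCatch(beta_at_pose(object, femur_transform = tf),
                    error = function(e) NULL)
    if (!is.null(res)) {
      out$beta_min[i] <- res$min_beta
      out$min_plane_index[i] <- res$min_plane_index
      out$n_usable_planes[i] <- sum(res$per_plane$usable)
    }
  }
  out
}

#' Plot per-plane beta angles
#'
#' @param x a `beta_result` from [min_beta()] or [beta_at_pose()].
#' @param ... passed to [plot()].
#' @export
plot.beta_result <- function(x, ...) {
  ok <- x$per_plane$usable
  graphics::plot(x$per_plane$offset_mm[ok], x$per_plane$beta_deg[ok],
                 type = "b", pch = 16,
                 xlab = "plane offset from alpha plane (mm)",
                 ylab = "beta (deg)", ...)
  graphics::abline(h = x$min_beta, lty = 2)
  invisible(x)
}
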