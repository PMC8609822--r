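#' Planes, slicing and in-plane projection
#'
#' A plane is stored as a point on the plane plus a unit normal. Planes are
#' used to reslice the positioned hip models parallel to the alpha plane.
#'
#' @param point numeric 3-vector on the plane (mm).
#' @param normal numeric 3-vector; normalised internally.
#' @return An object of class `hip_plane` with fields `point` and `normal`
#'   (unit length).
#' @export
hip_plane <- function(point, normal) {
  point <- as.numeric(point); stopifnot_finite(point, "plane point")
  structure(list(point = point, normal = unitize(as.numeric(normal), "plane normal")),
            class = "hip_plane")
}

#' @export
print.hip_plane <- function(x, ...) {
  cat(sprintf("<plane through (%.2f, %.2f, %.2f), normal (%.3f, %.3f, %.3f)>\n",
              x$point[1], x$point[2], x$point[3],
              x$normal[1], x$normal[2], x$normal[3]))
  invisible(x)
}

#' Signed distances from points to a plane
#'
#' @param cloud a [point_cloud()] or `n x 3` matrix.
#' @param plane a [hip_plane()].
#' @return Numeric vector of signed distances (mm, positive along the normal).
#' @export
plane_distance <- function(cloud, plane) {
  m <- if (inherits(cloud, "point_cloud")) as_cloud_matrix(cloud) else as.matrix(cloud)
  as.numeric(sweep(m, 2, plane$point, "-") %*% plane$normal)
}

#' Slice a cloud by a slab around a plane
#'
#' Keeps the points whose absolute signed distance to the plane is at most
#' `half_thickness` (closed slab; the boundary is included). Point order is
#' preserved; an empty result is valid.
#'
#' @inheritParams plane_distance
#' @param half_thickness slab half-thickness in mm (> 0).
#' @return A [point_cloud()] subset.
#' @export
slice_by_plane <- function(cloud, plane, half_thickness) {
  if (!is.numeric(half_thickness) || half_thickness <= 0) {
    stop("half_thickness must be > 0", call. = FALSE)
  }
  keep <- abs(plane_distance(cloud, plane)) <= half_thickness
  m <- if (inherits(cloud, "point_cloud")) as_cloud_matrix(cloud) else as.matrix(cloud)
  point_cloud(m[keep, , drop = FALSE], label = cloud_label(cloud))
}

#' Project points onto a plane
#'
#' Maps points to orthonormal in-plane coordinates. The returned basis makes
#' angles measured in the plane independent of the world frame; in-plane
#' distances are preserved (the projection restricted to the plane is an
#' isometry).
#'
#' @inheritParams plane_distance
#' @param u_hint optional 3-vector; the in-plane `u` axis is the normalised
#'   projection of this vector (default: a deterministic axis-derived basis).
#' @return A list with `coords` (`n x 2` matrix, columns `u`, `v`), `u`, `v`
#'   (3D basis vectors), `origin` (the plane point) and `out_of_plane` (signed
#'   distances of the original points).
#' @export
project_to_plane <- function(cloud, plane, u_hint = NULL) {
  n <- plane$normal
  if (is.null(u_hint)) {
    # pick the world axis least aligned with the normal
    e <- diag(3)[, which.min(abs(n))]
    u <- unitize(e - sum(e * n) * n, "in-plane basis")
  } else {
    u_hint <- as.numeric(u_hint)
    u_in <- u_hint - sum(u_hint * n) * n
    if (vnorm(u_in) < 1e-9) {
      stop("u_hint is (numerically) parallel to the plane normal", call. = FALSE)
    }
    u <- u_in / vnorm(u_in)
  }
  v <- cross3(n, u)
  m <- if (inherits(cloud, "point_cloud")) as_cloud_matrix(cloud) else
    matrix(as.numeric(cloud), ncol = 3)
  d <- sweep(m, 2, plane$point, "-")
  list(coords = cbind(u = as.numeric(d %*% u), v = as.numeric(d %*% v)),
       u = u, v = v, origin = plane$point,
       out_of_plane = as.numeric(d %*% n))
}

#' Reconstruct 3D points from in-plane coordinates
#'
#' Inverse of [project_to_plane()] for the projection feet.
#'
#' @param coords `n x 2` matrix of in-plane coordinates.
#' @param projection the list returned by [project_to_plane()].
#' @return `n x 3` matrix of 3D points lying on the plane.
#' @export
unproject_from_plane <- function(coords, projection) {
  coords <- matrix(as.numeric(coords), ncol = 2)
  sweep(coords[, 1, drop = FALSE] %*% rbind(projection$u) +
          coords[, 2, drop = FALSE] %*% rbind(projection$v),
        2, projection$origin, "+")
}

#' Least-squares sphere fit
#'
#' Fits a sphere to a point cloud by the linear algebraic (Coope) formulation,
#' then refines with Gauss-Newton iterations on the geometric residuals
#' `||p_i - c|| - r`. Deterministic; no random initialisation. Used for the
#' femoral head and the acetabular lunate surface.
#'
#' When `exclude_above` is set, points whose absolute geometric residual
#' exceeds that value (mm) are iteratively excluded and the sphere refitted
#' until the support set stabilises. This yields a sphere of the dominant
#' spherical (articular) surface even when a local prominence such as a cam
#' bump is present; the reported `rms_residual` refers to the retained
#' points.
#'
#' @param cloud a [point_cloud()] or `n x 3` matrix with at least 4
#'   non-coplanar points.
#' @param refine number of Gauss-Newton refinement iterations (0 disables).
#' @param exclude_above optional residual cut-off (mm) for iterative
#'   exclusion of off-sphere points.
#' @return An object of class `sphere_fit` with fields `center` (mm),
#'   `radius` (mm) and `rms_residual` (mm); attribute `n_used` gives the
#'   number of points supporting the final fit.
#' @examples
#' th <- acos(stats::runif(50, -1, 1)); ph <- stats::runif(50, 0, 2 * pi)
#' pts <- 5 * cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
#' fit_sphere(pts)
#' @export
fit_sphere <- function(cloud, refine = 25, exclude_above = NULL) {
  m <- if (inherits(cloud, "point_cloud")) as_cloud_matrix(cloud) else as.matrix(cloud)
  if (nrow(m) < 4) stop("sphere fit needs at least 4 points", call. = FALSE)
  if (!is.null(exclude_above)) {
    keep <- rep(TRUE, nrow(m))
    fit <- fit_sphere(m, refine = refine)
    for (it in 1:10) {
      res <- abs(sqrt(rowSums(sweep(m, 2, fit$center, "-")^2)) - fit$radius)
      new_keep <- res <= exclude_above
      if (sum(new_keep) < 4) break
      if (identical(new_keep, keep)) break
      keep <- new_keep
      fit <- fit_sphere(m[keep, , drop = FALSE], refine = refine)
    }
    attr(fit, "n_used") <- sum(keep)
    return(fit)
  }
  ctr <- colMeans(m)
  sv <- svd(sweep(m, 2, ctr, "-"), nu = 0, nv = 0)$d
  if (sv[3] < 1e-8 * max(sv[1], 1e-300)) {
    stop("degenerate geometry: points are (numerically) coplanar; ",
         "a sphere fit is not defined", call. = FALSE)
  }
  # Coope linearisation: ||p||^2 = 2 p.c + (r^2 - ||c||^2)
  A <- cbind(2 * m, 1)
  b <- rowSums(m^2)
  beta <- qr.solve(A, b)
  c0 <- beta[1:3]
  r0 <- sqrt(max(beta[4] + sum(c0^2), 0))
  # Gauss-Newton on geometric residuals
  cc <- c0; rr <- r0
  for (i in seq_len(refine)) {
    dvec <- sweep(m, 2, cc, "-")
    dn <- sqrt(rowSums(dvec^2))
    if (any(dn < 1e-12)) break
    res <- dn - rr
    J <- cbind(-dvec / dn, -1)
    step <- tryCatch(qr.solve(J, -res), error = function(e) NULL)
    if (is.null(step)) break
    cc <- cc + step[1:3]; rr <- rr + step[4]
    if (max(abs(step)) < 1e-12) break
  }
  if (rr <= 0) { cc <- c0; rr <- max(r0, 1e-9) }
  dn <- sqrt(rowSums(sweep(m, 2, cc, "-")^2))
  structure(list(center = as.numeric(cc), radius = rr,
                 rms_residual = sqrt(mean((dn - rr)^2))),
            n_used = nrow(m), class = "sphere_fit")
}

#' @export
print.sphere_fit <- function(x, ...) {
  cat(sprintf("<sphere_fit: center (%.3f, %.3f, %.3f) mm, radius %.3f mm, rms %.4f mm>\n",
              x$center[1], x$center[2], x$center[3], x$radius, x$rms_residual))
  invisible(x)
}

#' Principal-axis fit
#'
#' Returns the principal direction (direction of maximal variance) of a point
#' set through its centroid. Axes from point sets are sign-ambiguous; the
#' direction is oriented so that its dot product with `hint` is positive
#' (default hint: +y, the superior axis of the package's anatomical
#' convention). Used as a stand-in construction for femoral neck and shaft
#' axes when these are not supplied directly.
#'
#' @param cloud a [point_cloud()] or matrix with at least 2 points.
#' @param hint 3-vector fixing the canonical sign.
#' @param ratio_min minimum ratio between the two largest variances below
#'   which the direction is declared ambiguous.
#' @return An object of class `hip_axis` with fields `point` (the centroid)
#'   and `direction` (unit 3-vector).
#' @export
fit_axis <- function(cloud, hint = c(0, 1, 0), ratio_min = 1.05) {
  m <- if (inherits(cloud, "point_cloud")) as_cloud_matrix(cloud) else as.matrix(cloud)
  if (nrow(m) < 2) stop("axis fit needs at least 2 points", call. = FALSE)
  ctr <- colMeans(m)
  sv <- svd(sweep(m, 2, ctr, "-"), nu = 0, nv = 3)
  if (sv$d[1] < 1e-12) stop("degenerate geometry: all points coincide", call. = FALSE)
  if (sv$d[2] > 1e-12 && (sv$d[1] / sv$d[2])^2 < ratio_min) {
    stop("ambiguous axis: no dominant direction ",
         sprintf("(variance ratio %.3f < %.3f)", (sv$d[1] / sv$d[2])^2, ratio_min),
         call. = FALSE)
  }
  dir <- sv$v[, 1]
  s <- sum(dir * hint)
  if (abs(s) > 1e-12 && s < 0) dir <- -dir
  hip_axis(ctr, dir)
}

#' @rdname fit_axis
#' @param point point on the axis (mm).
#' @param direction axis direction; normalised internally.
#' @export
hip_axis <- function(point, direction) {
  structure(list(point = as.numeric(point),
                 direction = unitize(as.numeric(direction), "axis direction")),
            class = "hip_axis")
}

#' @export
print.hip_axis <- function(x, ...) {
  cat(sprintf("<axis through (%.2f, %.2f, %.2f), direction (%.3f, %.3f, %.3f)>\n",
              x$point[1], x$point[2], x$point[3],
              x$direction[1], x$direction[2], x$direction[3]))
  invisible(x)
}
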