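#' Parametric hip phantom specification
#'
#' Defines a synthetic proximal femur (spherical head, neck cylinder meeting
#' the head at the analytic sphere-cylinder junction, shaft stub, optional
#' Gaussian cam bump) and an acetabular cup (spherical-cap shell concentric
#' with the head) with closed-form clearance ground truth. All lengths in mm,
#' angles in degrees.
#'
#' @param head_radius femoral head radius (must exceed `neck_radius`).
#' @param neck_radius neck cylinder radius.
#' @param neck_length neck cylinder length beyond the junction.
#' @param neck_shaft_angle angle between neck and shaft axes.
#' @param cam_amplitude peak radial height of the cam bump (0 = spherical
#'   head).
#' @param cam_center_angle polar angle of the cam centre from the neck axis
#'   (deg); defaults to 12 deg beyond the sphere-cylinder junction.
#' @param cam_width Gaussian angular sigma of the cam bump (deg).
#' @param cup_coverage_angle half-angle of the acetabular cap around its pole
#'   (deg, in (0, 180)).
#' @param cup_clearance radial joint space between head and cup surfaces.
#' @param point_density surface sampling density (points per mm^2) for the
#'   head and cup; neck/shaft use half this density.
#' @param rim_line_density linear sampling density (points per mm) along the
#'   acetabular rim circle. The rim margin is a continuous bony edge visible
#'   in every image slice that crosses it, so it is sampled as a curve on
#'   top of the cap surface.
#' @param seed integer seed; generation is deterministic given the seed.
#' @return A list of class `hip_phantom_spec`.
#' @export
hip_phantom_spec <- function(head_radius = 25, neck_radius = 15,
                             neck_length = 40, neck_shaft_angle = 130,
                             cam_amplitude = 3, cam_center_angle = NULL,
                             cam_width = 12, cup_coverage_angle = 100,
                             cup_clearance = 0.5, point_density = 1.5,
                             rim_line_density = 4, seed = 1L) {
  if (!(head_radius > neck_radius && neck_radius > 0)) {
    stop("need head_radius > neck_radius > 0", call. = FALSE)
  }
  if (cam_amplitude < 0) stop("cam_amplitude must be >= 0", call. = FALSE)
  if (!(cup_coverage_angle > 0 && cup_coverage_angle < 180)) {
    stop("cup_coverage_angle must be in (0, 180)", call. = FALSE)
  }
  if (point_density <= 0) stop("point_density must be > 0", call. = FALSE)
  if (rim_line_density <= 0) stop("rim_line_density must be > 0", call. = FALSE)
  if (cam_width <= 0) stop("cam_width must be > 0", call. = FALSE)
  junction <- rad2deg(asin(neck_radius / head_radius))
  if (is.null(cam_center_angle)) cam_center_angle <- junction + 12
  structure(list(head_radius = head_radius, neck_radius = neck_radius,
                 neck_length = neck_length, neck_shaft_angle = neck_shaft_angle,
                 cam_amplitude = cam_amplitude,
                 cam_center_angle = cam_center_angle, cam_width = cam_width,
                 cup_coverage_angle = cup_coverage_angle,
                 cup_clearance = cup_clearance, point_density = point_density,
                 rim_line_density = rim_line_density,
                 seed = as.integer(seed)),
            class = "hip_phantom_spec")
}

# Analytic asphericity-onset angle (deg from the neck axis, in the alpha
# plane) for a given detection tolerance: the largest in-plane angle at which
# the contour exceeds head_radius + tolerance. With no (or sub-threshold)
# cam this is the cylinder flare asin(r_n / (R + tol)), which equals the
# sphere-cylinder junction angle at tolerance 0.
phantom_onset_angle <- function(spec, tolerance = 0.5) {
  cyl <- rad2deg(asin(spec$neck_radius / (spec$head_radius + tolerance)))
  if (spec$cam_amplitude > tolerance) {
    edge <- spec$cam_center_angle +
      spec$cam_width * sqrt(2 * log(spec$cam_amplitude / tolerance))
    max(cyl, edge)
  } else {
    cyl
  }
}

#' Generate a hip phantom
#'
#' Samples the phantom surfaces defined by a [hip_phantom_spec()] into point
#' clouds, places consistent anatomical landmarks (pelvis ASIS/PSIS,
#' epicondyles, head and acetabulum centres), and returns the closed-form
#' clearance ground truth. The phantom is built in the neutral anatomical
#' pose: pelvis frame axes equal the world axes (X anterior, Y superior, Z
#' right), head centre at the origin, femur frame aligned with the pelvis, so
#' the neutral hip angles are exactly (0, 0, 0) for a right hip.
#'
#' The analytic values: `junction_angle` is the sphere-cylinder junction
#' polar angle `asin(neck_radius / head_radius)`; `cup_edge_angle` is the
#' in-plane rim angle `180 - cup_coverage_angle` measured from the neck
#' direction; `onset_angle` is the asphericity-onset angle at `tolerance`;
#' `beta_true = cup_edge_angle - onset_angle` for the mid alpha plane at the
#' neutral pose.
#'
#' @param spec a [hip_phantom_spec()].
#' @param tolerance asphericity tolerance (mm) used for the analytic onset
#'   ground truth (match the tolerance passed to the clearance model).
#' @return A list of class `hip_phantom` with `femur`, `acetabulum`,
#'   `head_points` (the articular head subset used for sphere fitting),
#'   `landmarks`, `neck_axis`, `shaft_axis`, `alpha_plane`, `basis`
#'   (`u`, `v`, `normal` of the alpha-plane frame), `markers` (pelvis and
#'   thigh cluster templates), `analytic` and `spec`.
#' @export
generate_phantom <- function(spec, tolerance = 0.5) {
  stopifnot(inherits(spec, "hip_phantom_spec"))
  with_local_seed(spec$seed, {
    R <- spec$head_radius
    rn <- spec$neck_radius
    theta_j <- asin(rn / R)                      # junction polar angle (rad)
    # anatomical directions (right hip, neutral pose): the shaft runs along
    # -Y; the neck axis (head centre toward neck) is tilted from the distal
    # shaft by (180 - neck_shaft_angle) toward lateral (+Z), staying in the
    # frontal plane
    shaft_down <- c(0, -1, 0)
    tilt <- deg2rad(180 - spec$neck_shaft_angle)
    u <- unitize(c(0, -cos(tilt), sin(tilt)))
    normal <- unitize(cross3(u, c(0, 1, 0)))     # alpha plane normal (neck x shaft)
    v <- cross3(normal, u)                       # in-plane, cam side
    basis <- list(u = u, v = v, normal = normal)

    sphere_dir <- function(theta, psi) {
      # polar theta from u, azimuth psi from v around u
      outer(cos(theta), u) +
        outer(sin(theta) * cos(psi), v) +
        outer(sin(theta) * sin(psi), normal)
    }

    # femoral head: polar band [theta_j, pi], area-uniform
    n_head <- max(50L, round(2 * pi * R^2 * (cos(theta_j) + 1) * spec$point_density))
    ct <- stats::runif(n_head, -1, cos(theta_j))
    th <- acos(ct); ps <- stats::runif(n_head, 0, 2 * pi)
    dirs <- sphere_dir(th, ps)
    cam_dir <- cos(deg2rad(spec$cam_center_angle)) * u +
      sin(deg2rad(spec$cam_center_angle)) * v
    cosd <- pmin(1, pmax(-1, dirs %*% cam_dir))
    delta_deg <- rad2deg(acos(as.numeric(cosd)))
    radial <- R + spec$cam_amplitude * exp(-delta_deg^2 / (2 * spec$cam_width^2))
    head_pts <- dirs * radial

    # neck cylinder: axial [R cos(theta_j), + neck_length] along u
    half_density <- spec$point_density / 2
    n_neck <- max(30L, round(2 * pi * rn * spec$neck_length * half_density))
    tpos <- stats::runif(n_neck, R * cos(theta_j), R * cos(theta_j) + spec$neck_length)
    om <- stats::runif(n_neck, 0, 2 * pi)
    neck_pts <- outer(tpos, u) + rn * (outer(cos(om), v) + outer(sin(om), normal))

    # shaft stub along -Y from the neck end
    shaft_r <- 0.8 * rn; shaft_len <- 60
    q0 <- (R * cos(theta_j) + spec$neck_length) * u
    n_shaft <- max(30L, round(2 * pi * shaft_r * shaft_len * half_density))
    spos <- stats::runif(n_shaft, 0, shaft_len)
    so <- stats::runif(n_shaft, 0, 2 * pi)
    sperp1 <- c(1, 0, 0); sperp2 <- c(0, 0, 1)
    shaft_pts <- sweep(outer(spos, shaft_down) +
                         shaft_r * (outer(cos(so), sperp1) + outer(sin(so), sperp2)),
                       2, q0, "+")

    femur <- point_cloud(rbind(head_pts, neck_pts, shaft_pts), label = "femur")
    head_cloud <- point_cloud(head_pts, label = "femoral head")
    neck_cloud <- point_cloud(neck_pts, label = "femoral neck")
    shaft_cloud <- point_cloud(shaft_pts, label = "femoral shaft")

    # acetabular cup: cap of half-angle coverage around pole -u, concentric
    Rc <- R + spec$cup_clearance
    gam <- deg2rad(spec$cup_coverage_angle)
    n_cup <- max(30L, round(2 * pi * Rc^2 * (1 - cos(gam)) * spec$point_density))
    ctc <- stats::runif(n_cup, cos(gam), 1)
    thc <- acos(ctc); psc <- stats::runif(n_cup, 0, 2 * pi)
    cup_dirs <- outer(cos(thc), -u) +
      outer(sin(thc) * cos(psc), v) + outer(sin(thc) * sin(psc), normal)
    # rim margin: dense deterministic sampling of the cap edge circle
    n_rim <- max(16L, round(2 * pi * Rc * sin(gam) * spec$rim_line_density))
    tau <- seq(0, 2 * pi, length.out = n_rim + 1L)[-1L]
    rim_dirs <- outer(rep(cos(gam), n_rim), -u) +
      outer(sin(gam) * cos(tau), v) + outer(sin(gam) * sin(tau), normal)
    acetabulum <- point_cloud(Rc * rbind(cup_dirs, rim_dirs), label = "acetabulum")

    landmarks <- list(
      RASIS = c(60, 90, 35), LASIS = c(60, 90, -205),
      RPSIS = c(-95, 90, -25), LPSIS = c(-95, 90, -145),
      medial_epicondyle = c(0, -420, -45),
      lateral_epicondyle = c(0, -420, 45),
      femoral_head_center = c(0, 0, 0),
      acetabulum_center = c(0, 0, 0))

    markers <- list(
      pelvis = rbind(RASI = landmarks$RASIS, LASI = landmarks$LASIS,
                     RPSI = landmarks$RPSIS, LPSI = landmarks$LPSIS),
      thigh = rbind(THI1 = c(60, -150, 75), THI2 = c(85, -210, -15),
                    THI3 = c(15, -260, 85), THI4 = c(75, -310, 5)))

    onset <- phantom_onset_angle(spec, tolerance)
    cup_edge <- 180 - spec$cup_coverage_angle
    analytic <- list(junction_angle = rad2deg(theta_j),
                     cup_edge_angle = cup_edge,
                     onset_angle = onset,
                     beta_true = cup_edge - onset,
                     tolerance = tolerance)

    structure(list(
      femur = femur, acetabulum = acetabulum,
      head_points = head_cloud, neck_points = neck_cloud,
      shaft_points = shaft_cloud,
      landmarks = landmarks,
      neck_axis = hip_axis(c(0, 0, 0), u),
      shaft_axis = hip_axis(q0, c(0, 1, 0)),
      alpha_plane = hip_plane(c(0, 0, 0), normal),
      basis = basis, markers = markers,
      analytic = analytic, spec = spec),
      class = "hip_phantom")
  })
}

#' @export
print.hip_phantom <- function(x, ...) {
  cat(sprintf(
    "<hip_phantom: head R %.1f mm, cam %.1f mm, cup coverage %.0f deg; analytic beta %.2f deg>\n",
    x$spec$head_radius, x$spec$cam_amplitude, x$spec$cup_coverage_angle,
    x$analytic$beta_true))
  invisible(x)
}

#' Analytic beta angle of a posed phantom
#'
#' Closed-form beta in any plane of the reslicing stack when the phantom
#' femur is rotated by `rotation` about the head centre while the cup stays
#' fixed (the pelvis is the static body). All quantities are evaluated in the
#' femur-fixed alpha-plane basis, at plane offset `offset` mm along the
#' femur-fixed plane normal.
#'
#' Both the rim and the onset account for the finite slab: the clearance
#' model keeps every point within `half_thickness` of the plane, so the
#' ground truth evaluates the most advanced geometry available anywhere in
#' the slab. Rim: the cup cap meets the slab in an arc
#' `cos(phi - phi0) >= k(m') / w` (angles about the projected head centre,
#' slab coordinate `m'`); the rim is the arc endpoint on the marching side,
#' minimised over the slab, mirroring [find_rim_point()]. Onset: the largest
#' in-plane angle at which the contour exceeds the slice threshold radius
#' `sqrt(R^2 - h^2) + tolerance` — either the Gaussian cam bump's rising
#' edge or the neck cylinder flare, both in closed form, evaluated at the
#' most favourable slab coordinate `|h| - half_thickness`. `beta = rim -
#' onset`. Returns `NA` when the cap does not cross the slab (or covers the
#' whole slice circle) or when no onset exists in the slice.
#'
#' @param phantom a [generate_phantom()] result.
#' @param rotation 3x3 rotation applied to the femur (default identity,
#'   i.e. the neutral pose).
#' @param offset plane offset from the head centre along the alpha-plane
#'   normal (mm; 0 = mid plane).
#' @param tolerance asphericity tolerance (mm); defaults to the value stored
#'   at generation.
#' @param half_thickness slab half-thickness of the clearance model (mm).
#' @param slab `"favourable"` evaluates the most advanced geometry anywhere
#'   in the slab (the ideal limit a dense sampling attains); `"plane"`
#'   evaluates the slab's own coordinate only (the conservative limit). A
#'   finite point sampling detects onsets between the two, so together they
#'   bracket the discretised measurement.
#' @return Beta in degrees, or `NA`.
#' @export
phantom_analytic_beta <- function(phantom, rotation = diag(3), offset = 0,
                                  tolerance = phantom$analytic$tolerance,
                                  half_thickness = 0.5,
                                  slab = c("favourable", "plane")) {
  slab <- match.arg(slab)
  u <- phantom$basis$u; v <- phantom$basis$v; m <- phantom$basis$normal
  sp <- phantom$spec
  R <- sp$head_radius; h <- offset
  w_slab <- if (slab == "favourable") half_thickness else 0
  if (abs(h) >= R) return(NA_real_)
  rho_f <- sqrt(R^2 - h^2)                 # head circle radius in this plane
  rho_thr <- rho_f + tolerance             # in-plane onset threshold
  h_in <- max(abs(h) - w_slab, 0)          # most favourable slab coordinate

  # --- rim: cup cap arc endpoint, minimised over the slab -------------------
  Rc <- R + sp$cup_clearance
  c_f <- as.numeric(t(rotation) %*% (-u))  # cup pole in femur coordinates
  gam <- deg2rad(sp$cup_coverage_angle)
  a <- sum(c_f * u); b <- sum(c_f * v); cm <- sum(c_f * m)
  w <- sqrt(a^2 + b^2)
  if (w < 1e-12) return(NA_real_)
  phi0 <- rad2deg(atan2(b, a))
  rim_at <- function(mp) {
    if (abs(mp) >= Rc) return(NA_real_)
    k <- (Rc * cos(gam) - mp * cm) / sqrt(Rc^2 - mp^2)
    if (k > w) return(NA_real_)            # cap misses this slab layer
    if (k < -w) {
      # layer fully covered: as a lower bound the endpoint degenerates to
      # the antipode (favourable mode only; the plane mode treats a covered
      # slice as rim-free below)
      if (slab == "plane") return(NA_real_)
      k <- -w
    }
    phi0 - rad2deg(acos(max(-1, min(1, k / w))))
  }
  mp_grid <- seq(h - w_slab, h + w_slab, length.out = 9)
  rims <- vapply(mp_grid, rim_at, numeric(1))
  if (all(is.na(rims))) return(NA_real_)
  rim <- min(rims, na.rm = TRUE)
  if (slab == "plane") {
    # opening of the uncovered part of the slice circle; mirrors the minimum
    # circular gap accepted by find_rim_point()
    k0 <- (Rc * cos(gam) - h * cm) / sqrt(Rc^2 - h^2)
    span <- 2 * rad2deg(acos(max(-1, min(1, k0 / w))))
    if (360 - span < 20) return(NA_real_)
  }

  # --- onset: cam rising edge and/or neck cylinder flare --------------------
  onset <- -Inf
  # cam bump: a point at slab coordinate m' has in-plane radius
  # sqrt((R + bump)^2 - m'^2), supra-threshold once bump > b_req(m'); the
  # bump height depends on the angular distance to the cam centre,
  # cos(Delta) = sqrt(R^2 - m'^2) / R * cos(phi - theta_c)
  b_req <- sqrt(rho_thr^2 + h_in^2) - R
  if (b_req <= 0) return(NA_real_)  # guard-excluded near-tangent slice
  if (sp$cam_amplitude > b_req) {
    delta_edge <- deg2rad(sp$cam_width * sqrt(2 * log(sp$cam_amplitude / b_req)))
    cc <- cos(delta_edge) * R / sqrt(R^2 - h_in^2)
    if (cc <= 1) {
      onset <- max(onset, sp$cam_center_angle + rad2deg(acos(max(-1, cc))))
    }
  }
  # cylinder flare: points t*u + r_n(cos(om) v + sin(om) m) reach slab
  # coordinate m' = h_in when h_in < r_n; supra-threshold beyond t_sup, and
  # the cylinder starts at the junction t >= R cos(theta_j)
  rn <- sp$neck_radius
  if (h_in < rn) {
    q <- sqrt(rn^2 - h_in^2)
    t_sup <- sqrt(max(rho_thr^2 - q^2, 0))
    t_eff <- max(t_sup, sqrt(R^2 - rn^2))
    onset <- max(onset, rad2deg(atan2(q, t_eff)))
  }
  if (!is.finite(onset)) return(NA_real_)
  ((rim - onset + 90) %% 360) - 90   # same ray resolution as the measurement
}

#' Analytic minimum beta over a plane stack
#'
#' Evaluates [phantom_analytic_beta()] at the given plane offsets, drops
#' planes the clearance model would flag unusable (near-tangent slices whose
#' slab projection spread exceeds the tolerance), and returns the minimum —
#' the ground-truth counterpart of [min_beta()] for a posed phantom.
#'
#' @inheritParams phantom_analytic_beta
#' @param offsets numeric vector of plane offsets (mm).
#' @param half_thickness slab half-thickness used by the clearance model
#'   (mm), needed for the tangent-slice exclusion.
#' @return A list with `min_beta`, `offset_at_min` and `per_plane` (data
#'   frame `offset`, `beta`).
#' @export
phantom_analytic_min_beta <- function(phantom, rotation = diag(3),
                                      offsets, half_thickness = 0.5,
                                      tolerance = phantom$analytic$tolerance,
                                      slab = c("favourable", "plane")) {
  slab <- match.arg(slab)
  R <- phantom$spec$head_radius
  usable <- vapply(offsets, function(h) {
    if (abs(h) >= R) return(FALSE)
    inner <- max(abs(h) - half_thickness, 0)
    spread <- sqrt(max(R^2 - inner^2, 0)) - sqrt(R^2 - h^2)
    spread <= tolerance
  }, logical(1))
  beta <- rep(NA_real_, length(offsets))
  beta[usable] <- vapply(offsets[usable], function(h) {
    phantom_analytic_beta(phantom, rotation, offset = h, tolerance = tolerance,
                          half_thickness = half_thickness, slab = slab)
  }, numeric(1))
  if (all(is.na(beta))) {
    return(list(min_beta = NA_real_, offset_at_min = NA_real_,
                per_plane = data.frame(offset = offsets, beta = beta)))
  }
  i <- which.min(beta)
  list(min_beta = beta[i], offset_at_min = offsets[i],
       per_plane = data.frame(offset = offsets, beta = beta))
}
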