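# Shared fixture builders for the test suite. Everything is generated in
# code; no binary fixtures.

# Landmarks giving exactly axis-aligned pelvis and femur frames (right hip,
# X anterior, Y superior, Z right), origin at the hip centre.
aligned_landmarks <- function() {
  list(RASIS = c(60, 90, 35), LASIS = c(60, 90, -205),
       RPSIS = c(-95, 90, -25), LPSIS = c(-95, 90, -145),
       medial_epicondyle = c(0, -420, -45),
       lateral_epicondyle = c(0, -420, 45),
       femoral_head_center = c(0, 0, 0),
       acetabulum_center = c(0, 0, 0))
}

# Uniform samples on a sphere (area-uniform), deterministic under the
# caller's RNG state.
sphere_points <- function(n, center = c(0, 0, 0), radius = 1) {
  ct <- stats::runif(n, -1, 1)
  th <- acos(ct)
  ph <- stats::runif(n, 0, 2 * pi)
  sweep(radius * cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th)),
        2, center, "+")
}

# Random proper rotation via QR of a Gaussian matrix.
random_rotation <- function() {
  qrd <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qrd)
  Q %*% diag(c(1, 1, det(Q)))
}

random_rigid <- function(max_angle_deg = 45, max_trans = 20) {
  ax <- stats::rnorm(3)
  ang <- stats::runif(1, -max_angle_deg, max_angle_deg) * pi / 180
  u <- ax / sqrt(sum(ax^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
  rigid_transform(R, stats::runif(3, -max_trans, max_trans))
}

rot_z_oracle <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}
rot_x_oracle <- function(deg) {
  a <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}

# Angular sampling step (deg) of the phantom's head contour within one slab:
# points on the head circle band of width 2 * half_thickness.
phantom_angular_step <- function(spec, half_thickness = 0.5) {
  360 / (2 * pi * spec$head_radius * 2 * half_thickness * spec$point_density)
}

# Full simulated validation case: phantom + motion + fitted model + matched
# frame, shared by the end-to-end tests.
simulate_case <- function(seed, peak = c(85, 5, 5), kind = "squat",
                          cam_amplitude = 3, cup_coverage = 100,
                          noise_sd = 0, duration = 1, rate = 60,
                          target_fraction = 0.8) {
  spec <- hip_phantom_spec(cam_amplitude = cam_amplitude,
                           cup_coverage_angle = cup_coverage, seed = seed)
  phantom <- generate_phantom(spec)
  scenario <- motion_scenario(kind, peak_angles = peak, duration = duration,
                              rate = rate, marker_noise_sd = noise_sd,
                              seed = seed + 1000L)
  sim <- simulate_motion(scenario, phantom)
  model <- hip_model(phantom$femur, phantom$acetabulum, phantom$landmarks,
                     neck_axis = phantom$neck_points,
                     head_points = phantom$head_points)
  calib <- calibrate_standing(sim$motion, model$pelvis_frame,
                              model$femur_frame,
                              pelvis_markers = rownames(phantom$markers$pelvis),
                              thigh_markers = rownames(phantom$markers$thigh),
                              reference_distance = model$reference_distance)
  angles <- angles_per_frame(sim$motion, calib, side = "right")
  i_target <- max(1L, round(target_fraction * nrow(sim$truth)))
  target <- as.numeric(sim$truth[i_target,
                                 c("flexion", "adduction", "internal_rotation")])
  matched <- match_frame(angles, target)
  list(spec = spec, phantom = phantom, sim = sim, model = model,
       calib = calib, angles = angles, target = target,
       target_frame = i_target, matched = matched)
}
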