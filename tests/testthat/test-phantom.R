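# Synthetic hip phantom: analytic ground truth, determinism, simulation,
# fixture bundles.

test_that("phantom analytic values follow the closed-form geometry", {
  # no cam: onset is the cylinder flare; at tolerance 0 it is the junction
  sp0 <- hip_phantom_spec(cam_amplitude = 0, seed = 1)
  ph0 <- generate_phantom(sp0, tolerance = 0)
  expect_equal(ph0$analytic$junction_angle,
               asin(sp0$neck_radius / sp0$head_radius) * 180 / pi)
  expect_equal(ph0$analytic$onset_angle, ph0$analytic$junction_angle,
               tolerance = 1e-9)
  expect_equal(ph0$analytic$beta_true,
               (180 - sp0$cup_coverage_angle) - ph0$analytic$junction_angle,
               tolerance = 1e-9)

  ph0_tol <- generate_phantom(sp0, tolerance = 0.5)
  expect_equal(ph0_tol$analytic$onset_angle,
               asin(sp0$neck_radius / (sp0$head_radius + 0.5)) * 180 / pi)

  # supra-tolerance cam shifts the onset to the bump's rising edge
  spc <- hip_phantom_spec(cam_amplitude = 3, seed = 1)
  phc <- generate_phantom(spc, tolerance = 0.5)
  edge <- spc$cam_center_angle + spc$cam_width * sqrt(2 * log(3 / 0.5))
  expect_equal(phc$analytic$onset_angle, edge, tolerance = 1e-9)
  expect_lt(phc$analytic$beta_true, ph0_tol$analytic$beta_true)

  # sub-tolerance cam behaves like no cam
  sp_small <- hip_phantom_spec(cam_amplitude = 0.3, seed = 1)
  ph_small <- generate_phantom(sp_small, tolerance = 0.5)
  expect_equal(ph_small$analytic$onset_angle, ph0_tol$analytic$onset_angle)

  # the posed mid-plane formula agrees at the neutral pose (plane mode: the
  # favourable-slab mode is lower by the slab's rim spread)
  expect_equal(phantom_analytic_beta(phc, slab = "plane"),
               phc$analytic$beta_true, tolerance = 1e-9)
  expect_lte(phantom_analytic_beta(phc, slab = "favourable"),
             phc$analytic$beta_true)
})

test_that("phantom generation is deterministic given the seed", {
  a <- generate_phantom(hip_phantom_spec(seed = 77))
  b <- generate_phantom(hip_phantom_spec(seed = 77))
  expect_identical(unclass(a$femur), unclass(b$femur))
  c3 <- generate_phantom(hip_phantom_spec(seed = 78))
  expect_false(isTRUE(all.equal(unclass(a$femur), unclass(c3$femur))))
  expect_equal(a$analytic, c3$analytic)  # analytic truth is seed-free
  expect_error(generate_phantom(hip_phantom_spec(head_radius = 10,
                                                 neck_radius = 15)),
               "head_radius")
})

test_that("analytic beta is monotone in cam amplitude and cup coverage", {
  amps <- c(0.75, 1.5, 3, 6, 9)
  covs <- seq(88, 100, by = 3)
  beta_grid <- outer(amps, covs, Vectorize(function(A, cov) {
    generate_phantom(hip_phantom_spec(cam_amplitude = A,
                                      cup_coverage_angle = cov,
                                      seed = 1))$analytic$beta_true
  }))
  expect_true(all(apply(beta_grid, 2, diff) < 0))  # increasing cam
  expect_true(all(apply(beta_grid, 1, diff) < 0))  # increasing coverage
})

test_that("measured minimum beta matches the analytic value at neutral pose", {
  set.seed(61)
  for (i in 1:4) {
    A <- sample(c(0, 1.5, 3), 1)
    cov <- runif(1, 90, 100)
    spec <- hip_phantom_spec(cam_amplitude = A, cup_coverage_angle = cov,
                             seed = 60 + i)
    phantom <- generate_phantom(spec)
    model <- hip_model(phantom$femur, phantom$acetabulum, phantom$landmarks,
                       neck_axis = phantom$neck_points,
                       head_points = phantom$head_points)
    res <- beta_at_pose(model)
    truth <- phantom_analytic_min_beta(phantom, diag(3),
                                       res$per_plane$offset_mm)
    expect_lt(abs(res$min_beta - truth$min_beta),
              2 * phantom_angular_step(spec))
  }
})

test_that("zero-duration scenarios give one neutral frame", {
  phantom <- generate_phantom(hip_phantom_spec(point_density = 0.5, seed = 5))
  sim <- simulate_motion(motion_scenario("squat", duration = 0, rate = 120),
                         phantom)
  expect_equal(sim$motion$n_frames, 1)
  expect_equal(as.numeric(sim$truth[1, c("flexion", "adduction",
                                         "internal_rotation")]), c(0, 0, 0))
  calib <- calibrate_standing(sim$motion, sim$pelvis_frame, sim$femur_frame,
                              rownames(phantom$markers$pelvis),
                              rownames(phantom$markers$thigh))
  ang <- angles_per_frame(sim$motion, calib, side = "right")
  expect_lt(max(abs(c(ang$flexion, ang$adduction, ang$internal_rotation))),
            1e-9)
})

test_that("fixture bundles round-trip through disk", {
  phantom <- generate_phantom(hip_phantom_spec(point_density = 0.4, seed = 9))
  sim <- simulate_motion(motion_scenario("fadir", duration = 0.3, rate = 60,
                                         seed = 9), phantom)
  d <- withr::local_tempdir()
  files <- write_fixture_bundle(d, phantom, sim)
  expect_true(all(file.exists(files)))

  fem <- read_point_cloud(files[["femur"]])
  expect_equal(nrow(fem), nrow(phantom$femur))
  expect_lt(max(abs(unclass(fem) - unclass(phantom$femur))), 1e-3)
  lm <- read_landmarks(files[["landmarks"]])
  expect_equal(lm$RASIS, phantom$landmarks$RASIS)
  motion <- read_trc(files[["markers"]])
  expect_equal(motion$labels, sim$motion$labels)
  truth <- read.csv(files[["truth"]])
  expect_equal(truth$flexion, sim$truth$flexion, tolerance = 1e-9)
  meta <- jsonlite::read_json(files[["meta"]], simplifyVector = TRUE)
  expect_equal(meta$analytic$beta_true, phantom$analytic$beta_true,
               tolerance = 1e-8)
})
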