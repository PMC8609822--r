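# Clearance model: alpha plane, plane stack, sections, onset, rim, beta.

test_that("alpha plane contains the neck axis and rejects parallel axes", {
  head <- list(center = c(0, 0, 0), radius = 25)
  pl <- build_alpha_plane(head, hip_axis(c(0, 0, 0), c(1, 0, 0)),
                          hip_axis(c(0, 0, 0), c(0, 1, 0)))
  expect_equal(abs(pl$normal), c(0, 0, 1), ignore_attr = TRUE)
  expect_equal(pl$point, c(0, 0, 0))

  near <- hip_axis(c(0, 0, 0), c(cos(pi / 36), sin(pi / 36), 0))  # 5 deg away
  expect_silent(build_alpha_plane(head, hip_axis(c(0, 0, 0), c(1, 0, 0)), near))
  close4 <- hip_axis(c(0, 0, 0), c(cos(pi / 45), sin(pi / 45), 0))  # 4 deg
  expect_error(build_alpha_plane(head, hip_axis(c(0, 0, 0), c(1, 0, 0)), close4),
               "near-parallel")

  set.seed(29)
  for (i in 1:10) {
    n1 <- rnorm(3); n2 <- rnorm(3)
    pl2 <- tryCatch(build_alpha_plane(head, hip_axis(c(0, 0, 0), n1),
                                      hip_axis(c(0, 0, 0), n2)),
                    error = function(e) NULL)
    if (!is.null(pl2)) {
      expect_lt(abs(sum(pl2$normal * n1 / sqrt(sum(n1^2)))), 1e-9)
    }
  }
})

test_that("plane stacks enumerate symmetric offsets", {
  base <- hip_plane(c(0, 0, 0), c(0, 0, 1))
  st <- build_plane_stack(base, spacing = 2.5, count_each_side = 2)
  expect_equal(st$offsets, c(-5, -2.5, 0, 2.5, 5))
  expect_equal(length(st$planes), 5)
  # brute-force offset verification
  zs <- vapply(st$planes, function(p) p$point[3], numeric(1))
  expect_equal(zs, seq(-2, 2) * 2.5)

  st0 <- build_plane_stack(base, 2.5, 0)
  expect_equal(st0$offsets, 0)
  expect_error(build_plane_stack(base, -1, 2), "spacing")
  expect_error(build_plane_stack(base, 2.5, 2, half_thickness = 2), "<= spacing / 2")
})

test_that("sections flag unusable planes and slice like the brute force", {
  phantom <- generate_phantom(hip_phantom_spec(seed = 5))
  head <- fit_sphere(phantom$head_points, exclude_above = 0.5)
  far <- hip_plane(c(500, 0, 0), phantom$alpha_plane$normal)
  sec_far <- extract_section(phantom$femur, phantom$acetabulum, far, 0.5,
                             head, phantom$basis$u)
  expect_false(sec_far$usable)

  sec <- extract_section(phantom$femur, phantom$acetabulum,
                         phantom$alpha_plane, 0.5, head, phantom$basis$u)
  expect_true(sec$usable)
  expect_equal(sec$head_radius, head$radius, tolerance = 1e-9)
  # slicing equals the brute-force distance filter
  d <- abs((unclass(phantom$femur) %*% phantom$alpha_plane$normal) -
             sum(phantom$alpha_plane$point * phantom$alpha_plane$normal))
  expect_equal(nrow(sec$femur_2d), sum(d <= 0.5))
  # the femur contour contains the head-circle arc at the fitted radius
  on_head <- sec$femur_angle > 100 & sec$femur_angle < 170
  expect_gt(sum(on_head), 20)
  expect_lt(max(abs(sec$femur_radius[on_head] - sec$head_radius)), 0.6)
})

test_that("onset detection finds the cam edge and guards against spikes", {
  # synthetic section: exact circle -> no onset
  mk_section <- function(radii, angles, head_radius = 25) {
    structure(list(
      femur_2d = cbind(radii * cos(angles * pi / 180),
                       radii * sin(angles * pi / 180)),
      acetabulum_2d = cbind(-25, 0),
      femur_radius = radii, femur_angle = angles,
      acetabulum_angle = 180, head_center_2d = c(0, 0),
      head_radius = head_radius, usable = TRUE, reason = ""),
      class = "section_contour")
  }
  ang <- seq(5, 175, by = 1)
  circle <- mk_section(rep(25, length(ang)), ang)
  expect_false(find_asphericity_onset(circle, 0.5)$found)

  # single supra-threshold spike is ignored (run < 3)
  spiked <- rep(25, length(ang)); spiked[90] <- 26.5
  expect_false(find_asphericity_onset(mk_section(spiked, ang), 0.5)$found)

  # a genuine run is found at its largest angle
  r2 <- rep(25, length(ang)); r2[ang <= 60] <- 26
  onset <- find_asphericity_onset(mk_section(r2, ang), 0.5)
  expect_true(onset$found)
  expect_equal(onset$angle, 60)

  # phantom: onset within one angular sample of the analytic cam edge
  phantom <- generate_phantom(hip_phantom_spec(seed = 6))
  head <- fit_sphere(phantom$head_points, exclude_above = 0.5)
  sec <- extract_section(phantom$femur, phantom$acetabulum,
                         phantom$alpha_plane, 0.5, head, phantom$basis$u)
  got <- find_asphericity_onset(sec, 0.5)
  step <- phantom_angular_step(phantom$spec)
  expect_true(got$found)
  expect_lt(abs(got$angle - phantom$analytic$onset_angle), 2 * step)
})

test_that("rim detection returns the marching-side arc endpoint", {
  phantom <- generate_phantom(hip_phantom_spec(seed = 8))
  head <- fit_sphere(phantom$head_points, exclude_above = 0.5)
  sec <- extract_section(phantom$femur, phantom$acetabulum,
                         phantom$alpha_plane, 0.5, head, phantom$basis$u)
  rim <- find_rim_point(sec)
  expect_true(rim$found)
  expect_lt(abs(rim$angle - phantom$analytic$cup_edge_angle), 1)

  # single acetabular point -> that point
  single <- sec
  single$acetabulum_2d <- sec$acetabulum_2d[1, , drop = FALSE]
  single$acetabulum_angle <- sec$acetabulum_angle[1]
  r1 <- find_rim_point(single)
  expect_equal(r1$angle, sec$acetabulum_angle[1])

  # full-circle coverage -> no rim
  full <- sec
  full$acetabulum_angle <- seq(-179, 180, by = 1)
  full$acetabulum_2d <- cbind(cos(full$acetabulum_angle * pi / 180),
                              sin(full$acetabulum_angle * pi / 180)) * 25.5
  expect_false(find_rim_point(full)$found)

  # invariance under in-plane rotation of the basis: rotate hint
  sec2 <- extract_section(phantom$femur, phantom$acetabulum,
                          phantom$alpha_plane, 0.5, head,
                          phantom$basis$u,
                          direction_hint = phantom$basis$v)
  rim2 <- find_rim_point(sec2)
  expect_equal(rim2$angle, rim$angle, tolerance = 1e-9)
})

test_that("in-plane beta angle is signed by the marching direction", {
  sec <- structure(list(head_center_2d = c(0, 0)), class = "section_contour")
  rim <- c(cos(pi / 2), sin(pi / 2))          # 90 deg
  onset_beyond <- c(cos(80 * pi / 180), sin(80 * pi / 180))
  onset_under <- c(cos(100 * pi / 180), sin(100 * pi / 180))
  expect_equal(beta_angle_in_plane(sec, rim, rim), 0)
  expect_equal(beta_angle_in_plane(sec, onset_beyond, rim), 10,
               tolerance = 1e-9)
  expect_equal(beta_angle_in_plane(sec, onset_under, rim), -10,
               tolerance = 1e-9)
  expect_error(beta_angle_in_plane(sec, c(0, 0), rim), "degenerate")
})

test_that("min_beta is internally consistent and skips excluded planes", {
  phantom <- generate_phantom(hip_phantom_spec(seed = 10))
  head <- fit_sphere(phantom$head_points, exclude_above = 0.5)
  stack <- build_plane_stack(phantom$alpha_plane, 2.5,
                             ceiling(head$radius / 2.5), 0.5)
  res <- min_beta(phantom$femur, phantom$acetabulum, stack, head,
                  phantom$basis$u, tolerance = 0.5)
  ok <- res$per_plane$usable
  expect_true(any(ok))
  expect_equal(res$min_beta, min(res$per_plane$beta_deg[ok]))
  expect_true(all(is.na(res$per_plane$beta_deg[!ok])))
  expect_gt(length(res$excluded), 0)  # near-tangent planes are excluded
  # cam is centred on the mid plane, so the minimum occurs near it
  expect_lte(abs(res$min_plane_index), 1)
})

test_that("centre-to-centre adjustment translates along the centre line", {
  phantom <- generate_phantom(hip_phantom_spec(point_density = 0.3, seed = 2))
  head <- list(center = c(0, 0, 0), radius = 25)
  same <- adjust_center_distance(phantom$femur, head, c(50, 0, 0), 50)
  expect_equal(unclass(same$femur), unclass(phantom$femur), ignore_attr = TRUE)

  adj <- adjust_center_distance(phantom$femur, head, c(52, 0, 0), 50)
  expect_equal(adj$translation, c(2, 0, 0))
  expect_equal(sqrt(sum((adj$head_center - c(52, 0, 0))^2)), 50,
               tolerance = 1e-9)

  set.seed(33)
  for (i in 1:10) {
    ac <- rnorm(3, sd = 30); ref <- runif(1, 10, 60)
    out <- adjust_center_distance(phantom$femur, head, ac, ref)
    expect_equal(sqrt(sum((out$head_center - ac)^2)), ref, tolerance = 1e-9)
  }
  # coincident centres: zero reference is a no-op, nonzero is undefined
  noop <- adjust_center_distance(phantom$femur, head, c(0, 0, 0), 0)
  expect_equal(noop$translation, c(0, 0, 0))
  expect_error(adjust_center_distance(phantom$femur, head, c(0, 0, 0), 5),
               "undefined direction")
})

test_that("posed models honour ground-truth transforms and the reference distance", {
  case <- simulate_case(3, duration = 0.2, rate = 30)
  i <- case$matched$frame_index
  truth_tf <- case$sim$transforms[[i]]
  placed <- place_models_at_frame(case$phantom$femur, case$phantom$acetabulum,
                                  truth_tf$femur, truth_tf$pelvis,
                                  list(center = c(0, 0, 0), radius = 25),
                                  c(0, 0, 0), 0)
  direct <- apply_transform(case$phantom$femur, truth_tf$femur)
  expect_lt(max(abs(unclass(placed$femur) - unclass(direct))), 1e-9)
  expect_lt(sqrt(sum((placed$head_center - placed$acetabulum_center)^2)), 1e-9)
})

test_that("min_beta is invariant under a common rigid transform", {
  phantom <- generate_phantom(hip_phantom_spec(seed = 14))
  head <- fit_sphere(phantom$head_points, exclude_above = 0.5)
  stack <- build_plane_stack(phantom$alpha_plane, 2.5, 4, 0.5)
  base <- min_beta(phantom$femur, phantom$acetabulum, stack, head,
                   phantom$basis$u, tolerance = 0.5)
  set.seed(35)
  tr <- random_rigid(40, 50)
  fem2 <- apply_transform(phantom$femur, tr)
  ace2 <- apply_transform(phantom$acetabulum, tr)
  head2 <- list(center = as.numeric(tr$rotation %*% head$center) + tr$translation,
                radius = head$radius)
  base2 <- hip_plane(as.numeric(tr$rotation %*% phantom$alpha_plane$point) +
                       tr$translation,
                     as.numeric(tr$rotation %*% phantom$alpha_plane$normal))
  stack2 <- build_plane_stack(base2, 2.5, 4, 0.5)
  moved <- min_beta(fem2, ace2, stack2, head2,
                    as.numeric(tr$rotation %*% phantom$basis$u), tolerance = 0.5)
  expect_equal(moved$min_beta, base$min_beta, tolerance = 1e-6)
  expect_equal(moved$min_plane_index, base$min_plane_index)
})
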