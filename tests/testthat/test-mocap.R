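# Motion-capture pipeline: TRC IO, calibration, per-frame angles, matching.

test_that("TRC files round-trip and regenerate byte-identically", {
  phantom <- generate_phantom(hip_phantom_spec(point_density = 0.3, seed = 4))
  sim <- simulate_motion(motion_scenario("squat", duration = 0.3, rate = 60,
                                         marker_noise_sd = 0.5, seed = 7),
                         phantom)
  d <- withr::local_tempdir()
  f1 <- file.path(d, "a.trc"); f2 <- file.path(d, "b.trc")
  write_trc(sim$motion, f1)
  got <- read_trc(f1)
  expect_equal(got$labels, sim$motion$labels)
  expect_equal(got$rate, sim$motion$rate)
  expect_lt(max(abs(got$positions - sim$motion$positions)), 1e-4)

  # identical seed -> byte-identical file
  sim2 <- simulate_motion(motion_scenario("squat", duration = 0.3, rate = 60,
                                          marker_noise_sd = 0.5, seed = 7),
                          phantom)
  write_trc(sim2$motion, f2)
  expect_identical(readLines(f1)[-1], readLines(f2)[-1])  # line 1 holds the name
})

test_that("standing calibration round-trips and rejects degenerate clusters", {
  phantom <- generate_phantom(hip_phantom_spec(seed = 6))
  sim <- simulate_motion(motion_scenario("squat", duration = 0.2, rate = 30),
                         phantom)
  calib <- calibrate_standing(sim$motion, sim$pelvis_frame, sim$femur_frame,
                              rownames(phantom$markers$pelvis),
                              rownames(phantom$markers$thigh))
  # reconstructing the anatomical frames from the calibration frame itself
  ang <- angles_per_frame(sim$motion, calib, side = "right")
  expect_false(ang$gap[1])
  expect_lt(max(abs(c(ang$flexion[1], ang$adduction[1],
                      ang$internal_rotation[1]))), 1e-9)

  # moving markers and frames together leaves the calibration invariant
  set.seed(41)
  tr <- random_rigid(30, 50)
  moved_markers <- rbind(apply_transform(calib$pelvis_markers, tr),
                         apply_transform(calib$thigh_markers, tr))
  calib2 <- calibrate_standing(moved_markers,
                               frame_pose(calib$pelvis_frame, tr),
                               frame_pose(calib$femur_frame, tr),
                               rownames(calib$pelvis_markers),
                               rownames(calib$thigh_markers))
  expect_equal(calib2$reference_distance, calib$reference_distance,
               tolerance = 1e-9)

  two <- calib$pelvis_markers[1:2, ]
  expect_error(
    calibrate_standing(rbind(two, calib$thigh_markers),
                       calib$pelvis_frame, calib$femur_frame,
                       rownames(two), rownames(calib$thigh_markers)),
    ">= 3")
  line <- rbind(A = c(0, 0, 0), B = c(1, 0, 0), C = c(2, 0, 0))
  expect_error(
    calibrate_standing(rbind(line, calib$thigh_markers),
                       calib$pelvis_frame, calib$femur_frame,
                       c("A", "B", "C"), rownames(calib$thigh_markers)),
    "collinear")
})

test_that("noise-free simulated motion is recovered to numerical precision", {
  # calibrate with the simulator's exact anatomical frames: the marker chain
  # itself (cluster fits, frame propagation, angle decomposition) is exact
  phantom <- generate_phantom(hip_phantom_spec(seed = 7))
  sim <- simulate_motion(motion_scenario("squat", peak_angles = c(85, 5, 5),
                                         duration = 0.5, rate = 60), phantom)
  calib <- calibrate_standing(sim$motion, sim$pelvis_frame, sim$femur_frame,
                              rownames(phantom$markers$pelvis),
                              rownames(phantom$markers$thigh))
  ang <- angles_per_frame(sim$motion, calib, side = "right")
  expect_false(any(ang$gap))
  expect_lt(max(abs(ang$flexion - sim$truth$flexion)), 1e-6)
  expect_lt(max(abs(ang$adduction - sim$truth$adduction)), 1e-6)
  expect_lt(max(abs(ang$internal_rotation - sim$truth$internal_rotation)),
            1e-6)

  # with frames fitted from the sampled clouds the residual is the anatomy
  # fitting error, still far below a tenth of a degree
  case <- simulate_case(7, peak = c(85, 5, 5), duration = 0.5, rate = 60)
  expect_lt(max(abs(case$angles$flexion - case$sim$truth$flexion)), 0.05)
})

test_that("marker noise of 1 mm keeps angle RMS below 1 degree", {
  case <- simulate_case(8, noise_sd = 1, duration = 1, rate = 60)
  ang <- case$angles
  err2 <- (ang$flexion - case$sim$truth$flexion)^2 +
    (ang$adduction - case$sim$truth$adduction)^2 +
    (ang$internal_rotation - case$sim$truth$internal_rotation)^2
  expect_lt(sqrt(mean(err2) / 3), 1)
})

test_that("frames with missing markers become gaps, never interpolations", {
  case <- simulate_case(9, duration = 0.2, rate = 30)
  motion <- case$sim$motion
  motion$positions[3, , rownames(case$phantom$markers$thigh)[1:2]] <- NA
  ang <- angles_per_frame(motion, case$calib, side = "right")
  expect_true(ang$gap[3])
  expect_true(is.na(ang$flexion[3]))
  expect_false(any(ang$gap[-3]))
})

test_that("match_frame equals the exhaustive scan with earliest-index ties", {
  case <- simulate_case(10, duration = 0.5, rate = 60)
  ang <- case$angles
  target <- c(ang$flexion[17], ang$adduction[17], ang$internal_rotation[17])
  hit <- match_frame(ang, target)
  expect_equal(hit$frame_index, 17)
  expect_lt(hit$lsqe, 1e-12)

  set.seed(43)
  for (i in 1:10) {
    tgt <- c(runif(1, 0, 90), runif(1, -10, 10), runif(1, -10, 10))
    got <- match_frame(ang, tgt)
    brute <- sqrt((ang$flexion - tgt[1])^2 + (ang$adduction - tgt[2])^2 +
                    (ang$internal_rotation - tgt[3])^2)
    expect_equal(got$frame_index, which.min(brute))
    expect_equal(got$lsqe, min(brute))
    expect_true(all(got$lsqe <= brute))
  }

  # duplicated frames tie -> earliest index
  dup <- ang[c(1, 1, 2), ]; dup$frame <- 1:3
  tie <- match_frame(dup, c(dup$flexion[1], dup$adduction[1],
                            dup$internal_rotation[1]))
  expect_equal(tie$frame_index, 1)

  allgap <- ang; allgap$gap <- TRUE
  expect_error(match_frame(allgap, tgt), "no valid")
})
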