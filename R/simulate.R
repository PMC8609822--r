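#' Motion scenario specification
#'
#' Describes a simulated squat or sitting-FADIR trial: a smooth half-cosine
#' ramp of the hip angles from the neutral standing pose to the peak triple,
#' with markers rigidly attached to the phantom bodies and optional isotropic
#' Gaussian marker noise.
#'
#' @param kind `"squat"` or `"fadir"` (labelling only; both are angle ramps).
#' @param peak_angles [hip_angles()] or numeric triple (flexion, adduction,
#'   internal rotation, deg) reached at the final frame. Defaults emulate a
#'   deep squat (85, 5, 5) or a FADIR pose (90, 10, 18).
#' @param duration trial duration in seconds (0 gives a single neutral
#'   frame).
#' @param rate sampling rate in Hz.
#' @param marker_noise_sd isotropic Gaussian marker noise SD (mm, per axis,
#'   independent per frame; 0 = noise-free).
#' @param seed integer seed for the noise.
#' @return A list of class `motion_scenario`.
#' @export
motion_scenario <- function(kind = c("squat", "fadir"), peak_angles = NULL,
                            duration = 2, rate = 120, marker_noise_sd = 0,
                            seed = 1L) {
  kind <- match.arg(kind)
  if (is.null(peak_angles)) {
    peak_angles <- if (kind == "squat") c(85, 5, 5) else c(90, 10, 18)
  }
  peak_angles <- as.numeric(peak_angles)[1:3]
  if (rate <= 0) stop("rate must be > 0", call. = FALSE)
  if (duration < 0) stop("duration must be >= 0", call. = FALSE)
  if (marker_noise_sd < 0) stop("marker_noise_sd must be >= 0", call. = FALSE)
  structure(list(kind = kind, peak_angles = peak_angles, duration = duration,
                 rate = rate, marker_noise_sd = marker_noise_sd,
                 seed = as.integer(seed)),
            class = "motion_scenario")
}

#' Simulate a motion-capture trial on a phantom
#'
#' Composes per-frame femur poses from a half-cosine angle ramp (pelvis held
#' static, rotation about the femoral head centre), rigidly carries the
#' pelvis and thigh marker clusters, adds optional marker noise, and records
#' the rigid-body ground truth: true angles, true supine-to-frame transforms,
#' and the analytic beta angle per frame.
#'
#' @param scenario a [motion_scenario()].
#' @param phantom a [generate_phantom()] result.
#' @return A list with `motion` (a [marker_trajectories()]), `truth` (data
#'   frame `frame`, `time`, `flexion`, `adduction`, `internal_rotation`,
#'   `beta_true`), `transforms` (per-frame list of `list(pelvis =, femur =)`
#'   true [rigid_transform()]s), `pelvis_frame`, `femur_frame` (neutral
#'   anatomical frames) and `scenario`.
#' @export
simulate_motion <- function(scenario, phantom) {
  stopifnot(inherits(scenario, "motion_scenario"), inherits(phantom, "hip_phantom"))
  pelvis_frame <- build_pelvis_frame(phantom$landmarks)
  femur_frame <- build_femur_frame(phantom$landmarks,
                                   list(center = phantom$landmarks$femoral_head_center))
  n <- max(1L, as.integer(round(scenario$duration * scenario$rate)))
  s <- if (n == 1L) 0 else (1 - cos(pi * (seq_len(n) - 1) / (n - 1))) / 2
  ang <- outer(s, scenario$peak_angles)
  labels <- c(rownames(phantom$markers$pelvis), rownames(phantom$markers$thigh))
  arr <- array(NA_real_, c(n, 3, length(labels)))
  transforms <- vector("list", n)
  beta_true <- numeric(n)
  head <- phantom$landmarks$femoral_head_center
  for (i in seq_len(n)) {
    fr <- compose_hip_angles(pelvis_frame,
                             hip_angles(ang[i, 1], ang[i, 2], ang[i, 3]),
                             origin = head)
    Rw <- fr$axes %*% t(femur_frame$axes)   # neutral femur axes -> frame i
    tf <- rigid_transform(Rw, head - as.numeric(Rw %*% head))
    tp <- rigid_transform()                 # static pelvis
    transforms[[i]] <- list(pelvis = tp, femur = tf)
    pel_m <- phantom$markers$pelvis
    thi_m <- apply_transform(phantom$markers$thigh, tf)
    arr[i, , ] <- t(rbind(pel_m, thi_m))
    beta_true[i] <- phantom_analytic_beta(phantom, rotation = Rw)
  }
  if (scenario$marker_noise_sd > 0) {
    arr <- with_local_seed(scenario$seed,
      arr + stats::rnorm(length(arr), sd = scenario$marker_noise_sd))
  }
  motion <- marker_trajectories(arr, labels = labels, rate = scenario$rate)
  truth <- data.frame(frame = seq_len(n), time = (seq_len(n) - 1) / scenario$rate,
                      flexion = ang[, 1], adduction = ang[, 2],
                      internal_rotation = ang[, 3], beta_true = beta_true)
  list(motion = motion, truth = truth, transforms = transforms,
       pelvis_frame = pelvis_frame, femur_frame = femur_frame,
       scenario = scenario)
}

#' Write a phantom + motion fixture bundle to disk
#'
#' Writes ASCII PLY bone clouds, a landmark JSON, a TRC marker file, a
#' ground-truth CSV and a metadata JSON so a complete synthetic validation
#' case can be run through the file-based interface. Re-reading reproduces
#' the inputs at the written precision.
#'
#' @param path output directory (created if needed).
#' @param phantom a [generate_phantom()] result.
#' @param simulation a [simulate_motion()] result.
#' @return Named character vector of the written file paths, invisibly.
#' @export
write_fixture_bundle <- function(path, phantom, simulation) {
  ok <- dir.exists(path) || dir.create(path, recursive = TRUE)
  if (!ok) stop("cannot create output directory: ", path, call. = FALSE)
  files <- c(femur = file.path(path, "femur.ply"),
             acetabulum = file.path(path, "acetabulum.ply"),
             head = file.path(path, "femoral_head.ply"),
             landmarks = file.path(path, "landmarks.json"),
             markers = file.path(path, "markers.trc"),
             truth = file.path(path, "ground_truth.csv"),
             meta = file.path(path, "meta.json"))
  wrap <- function(f, target) {
    tryCatch(f(), error = function(e) {
      stop("failed writing ", target, ": ", conditionMessage(e), call. = FALSE)
    })
  }
  wrap(function() write_point_cloud(phantom$femur, files[["femur"]], format = "ply"),
       files[["femur"]])
  wrap(function() write_point_cloud(phantom$acetabulum, files[["acetabulum"]],
                                    format = "ply"), files[["acetabulum"]])
  wrap(function() write_point_cloud(phantom$head_points, files[["head"]],
                                    format = "ply"), files[["head"]])
  wrap(function() write_landmarks(phantom$landmarks, files[["landmarks"]]),
       files[["landmarks"]])
  wrap(function() write_trc(simulation$motion, files[["markers"]]),
       files[["markers"]])
  wrap(function() utils::write.csv(simulation$truth, files[["truth"]],
                                   row.names = FALSE), files[["truth"]])
  meta <- list(spec = unclass(phantom$spec),
               analytic = phantom$analytic,
               scenario = unclass(simulation$scenario),
               pelvis_markers = rownames(phantom$markers$pelvis),
               thigh_markers = rownames(phantom$markers$thigh),
               package_version = as.character(utils::packageVersion("hipclear")))
  wrap(function() jsonlite::write_json(meta, files[["meta"]], digits = 10,
                                       auto_unbox = TRUE), files[["meta"]])
  invisible(files)
}
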