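#' Run the full validation pipeline from a configuration
#'
#' End-to-end reproduction of the validation workflow for one subject:
#' standing calibration from the first motion frame, hip angles for every
#' frame, matching of the imaged target posture by least-squares angle error,
#' posing of the bone models at the matched frame with the centre-to-centre
#' adjustment, minimum beta over the alpha-plane stack, and (when a directly
#' measured reference beta is supplied) the absolute prediction error.
#'
#' @param config a named list, or a path to a YAML/JSON file with the same
#'   fields: `femur`, `acetabulum`, `neck` (point cloud paths; `head`
#'   optional, defaults to `femur`), `landmarks` (JSON/CSV path), `motion`
#'   (TRC path), `pelvis_markers`, `thigh_markers` (label vectors), `side`,
#'   `target` (imaged hip angles, numeric triple in degrees), optional
#'   `reference_beta` (deg), optional numeric settings `spacing` (default
#'   2.5), `slab` (0.5), `tolerance` (0.5), optional `calibration_frame`
#'   (default 1) and `out_dir`.
#' @return A list of class `pipeline_report`: `matched_frame`, `lsqe`,
#'   `angles` (per-frame data frame), `beta` (a `beta_result`),
#'   `beta_predicted`, `reference_beta`, `abs_error`, `model` (the fitted
#'   [hip_model()]), `config` (echo), `config_hash`, `package_version` and
#'   `files` (paths written, if `out_dir` was set).
#' @export
run_full_pipeline <- function(config) {
  if (is.character(config)) {
    ext <- tolower(tools::file_ext(config))
    config <- if (ext %in% c("yml", "yaml")) yaml::read_yaml(config)
    else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- utils::modifyList(
    list(head = NULL, side = "right", spacing = 2.5, slab = 0.5,
         tolerance = 0.5, reference_beta = NULL, calibration_frame = 1L,
         out_dir = NULL, alpha = 0.05),
    config[!vapply(config, is.null, logical(1))])
  # validate settings before touching any file
  for (key in c("spacing", "slab", "tolerance")) {
    if (!is.numeric(cfg[[key]]) || cfg[[key]] <= 0) {
      stop("config error: '", key, "' must be a positive number", call. = FALSE)
    }
  }
  for (key in c("femur", "acetabulum", "neck", "landmarks", "motion",
                "pelvis_markers", "thigh_markers", "target")) {
    if (is.null(cfg[[key]])) stop("config error: missing field '", key, "'",
                                  call. = FALSE)
  }
  cfg$target <- as.numeric(cfg$target)
  if (length(cfg$target) != 3 || !all(is.finite(cfg$target))) {
    stop("config error: 'target' must be three finite angles (deg)", call. = FALSE)
  }

  femur <- read_point_cloud(cfg$femur)
  acetabulum <- read_point_cloud(cfg$acetabulum)
  head_pts <- if (is.null(cfg$head)) femur else read_point_cloud(cfg$head)
  neck_pts <- read_point_cloud(cfg$neck)
  landmarks <- read_landmarks(cfg$landmarks)
  motion <- read_trc(cfg$motion)

  model <- hip_model(femur, acetabulum, landmarks, neck_axis = neck_pts,
                     head_points = head_pts, side = cfg$side,
                     spacing = cfg$spacing, half_thickness = cfg$slab,
                     tolerance = cfg$tolerance)

  calib <- calibrate_standing(motion, model$pelvis_frame, model$femur_frame,
                              pelvis_markers = cfg$pelvis_markers,
                              thigh_markers = cfg$thigh_markers,
                              reference_distance = model$reference_distance,
                              frame = cfg$calibration_frame)
  angles <- angles_per_frame(motion, calib, side = cfg$side)
  m <- match_frame(angles, cfg$target)
  tfs <- attr(angles, "transforms")[[m$frame_index]]
  beta <- beta_at_pose_transforms(model, tfs$femur, tfs$pelvis)

  abs_error <- if (!is.null(cfg$reference_beta)) {
    abs(beta$min_beta - as.numeric(cfg$reference_beta))
  } else NA_real_

  cfg_echo <- cfg[order(names(cfg))]
  tmp <- tempfile(); on.exit(unlink(tmp), add = TRUE)
  saveRDS(cfg_echo, tmp)
  report <- list(matched_frame = m$frame_index, lsqe = m$lsqe,
                 angles = angles, beta = beta,
                 beta_predicted = beta$min_beta,
                 reference_beta = if (is.null(cfg$reference_beta)) NA_real_
                 else as.numeric(cfg$reference_beta),
                 abs_error = abs_error,
                 model = model, config = cfg_echo,
                 config_hash = unname(tools::md5sum(tmp)),
                 package_version = as.character(utils::packageVersion("hipclear")))
  class(report) <- "pipeline_report"
  if (!is.null(cfg$out_dir)) report$files <- write_pipeline_report(report, cfg$out_dir)
  report
}

# beta_at_pose for externally supplied transforms (shared by pipeline and
# beta_at_pose); kept separate so hip_model stays independent of mocap.
beta_at_pose_transforms <- function(model, femur_transform, pelvis_transform) {
  beta_at_pose(model, femur_transform = femur_transform,
               pelvis_transform = pelvis_transform)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Hip clearance pipeline report\n")
  cat(sprintf("  matched frame: %d (LSQE %.3f deg)\n", x$matched_frame, x$lsqe))
  cat(sprintf("  predicted minimum beta: %.2f deg (plane %d)\n",
              x$beta_predicted, x$beta$min_plane_index))
  if (is.finite(x$abs_error)) {
    cat(sprintf("  reference beta: %.2f deg  ->  absolute error %.2f deg\n",
                x$reference_beta, x$abs_error))
  }
  invisible(x)
}

write_pipeline_report <- function(report, out_dir) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  files <- c(report = file.path(out_dir, "report.json"),
             angles = file.path(out_dir, "angles.csv"),
             beta = file.path(out_dir, "beta_per_plane.csv"))
  utils::write.csv(report$angles, files[["angles"]], row.names = FALSE)
  utils::write.csv(report$beta$per_plane, files[["beta"]], row.names = FALSE)
  json <- list(matched_frame = report$matched_frame, lsqe = report$lsqe,
               beta_predicted = report$beta_predicted,
               min_plane_index = report$beta$min_plane_index,
               reference_beta = report$reference_beta,
               abs_error = report$abs_error,
               settings = report$beta$settings,
               excluded_planes = report$beta$excluded,
               config = report$config[!vapply(report$config, is.null, logical(1))],
               config_hash = report$config_hash,
               package_version = report$package_version)
  jsonlite::write_json(json, files[["report"]], digits = 10, auto_unbox = TRUE,
                       null = "null")
  files
}
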