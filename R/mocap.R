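#' Marker trajectories
#'
#' Labelled marker positions over time at a fixed sample rate. Stored as a
#' 3D array `[frame, axis, marker]` (mm); missing samples (gaps) are `NA`.
#'
#' @param positions numeric array `n_frames x 3 x n_markers`, or a list of
#'   per-marker `n_frames x 3` matrices.
#' @param labels marker names (unique); taken from `dimnames` if omitted.
#' @param rate sampling rate in Hz (> 0).
#' @return An object of class `marker_trajectories`.
#' @export
marker_trajectories <- function(positions, labels = NULL, rate = 120) {
  if (is.list(positions)) {
    labels <- labels %||% names(positions)
    arr <- array(NA_real_, c(nrow(positions[[1]]), 3, length(positions)))
    for (i in seq_along(positions)) arr[, , i] <- as.matrix(positions[[i]])
    positions <- arr
  }
  if (length(dim(positions)) != 3 || dim(positions)[2] != 3) {
    stop("positions must be an n_frames x 3 x n_markers array", call. = FALSE)
  }
  if (is.null(labels)) labels <- dimnames(positions)[[3]]
  if (is.null(labels) || anyDuplicated(labels)) {
    stop("marker labels must be present and unique", call. = FALSE)
  }
  if (!is.numeric(rate) || rate <= 0) stop("rate must be > 0", call. = FALSE)
  dimnames(positions) <- list(NULL, c("x", "y", "z"), labels)
  structure(list(positions = positions, labels = labels, rate = rate,
                 n_frames = dim(positions)[1]),
            class = "marker_trajectories")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.marker_trajectories <- function(x, ...) {
  cat(sprintf("<marker_trajectories: %d markers x %d frames at %g Hz>\n",
              length(x$labels), x$n_frames, x$rate))
  invisible(x)
}

# Named 3 x m matrix of one frame's marker positions (columns = labels).
frame_markers <- function(motion, frame, labels = motion$labels) {
  miss <- setdiff(labels, motion$labels)
  if (length(miss)) {
    stop("markers not present in trajectories: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  m <- t(motion$positions[frame, , labels, drop = TRUE])
  if (length(labels) == 1L) m <- matrix(motion$positions[frame, , labels], 1, 3)
  rownames(m) <- labels
  m
}

#' Read and write TRC marker files
#'
#' Minimal reader/writer for the tab-separated TRC motion-capture format
#' (standard header with `DataRate`/`NumFrames`/`NumMarkers`/`Units`,
#' `Frame#`/`Time` columns, then X/Y/Z triples per marker). Units other than
#' mm are converted to mm on read.
#'
#' @param path file path.
#' @return A [marker_trajectories()].
#' @export
read_trc <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 6) stop("malformed TRC file ", path, ": too short", call. = FALSE)
  hdr_names <- strsplit(lines[2], "\t")[[1]]
  hdr_vals <- strsplit(lines[3], "\t")[[1]]
  hdr <- stats::setNames(as.list(hdr_vals), hdr_names)
  rate <- as.numeric(hdr[["DataRate"]] %||% hdr_vals[1])
  units <- hdr[["Units"]] %||% "mm"
  marker_line <- strsplit(lines[4], "\t")[[1]]
  labels <- marker_line[-(1:2)]
  labels <- labels[nzchar(trimws(labels))]
  data_lines <- lines[-(1:5)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  rows <- lapply(data_lines, function(l) {
    suppressWarnings(as.numeric(strsplit(l, "\t")[[1]]))
  })
  ncol_expect <- 2 + 3 * length(labels)
  rows <- lapply(rows, function(r) { length(r) <- ncol_expect; r })
  m <- do.call(rbind, rows)
  scale <- switch(tolower(units), mm = 1, m = 1000, cm = 10, 1)
  arr <- array(NA_real_, c(nrow(m), 3, length(labels)))
  for (j in seq_along(labels)) {
    arr[, , j] <- m[, (3 * j):(3 * j + 2), drop = FALSE] * scale
  }
  marker_trajectories(arr, labels = labels, rate = rate)
}

#' @rdname read_trc
#' @param motion a [marker_trajectories()].
#' @param digits decimal places written.
#' @export
write_trc <- function(motion, path, digits = 5) {
  n <- motion$n_frames; m <- length(motion$labels)
  l1 <- sprintf("PathFileType\t4\t(X/Y/Z)\t%s", basename(path))
  l2 <- "DataRate\tCameraRate\tNumFrames\tNumMarkers\tUnits\tOrigDataRate\tOrigDataStartFrame\tOrigNumFrames"
  l3 <- sprintf("%g\t%g\t%d\t%d\tmm\t%g\t1\t%d", motion$rate, motion$rate, n, m,
                motion$rate, n)
  l4 <- paste(c("Frame#", "Time",
                as.vector(rbind(motion$labels, "", ""))), collapse = "\t")
  l5 <- paste(c("", "", paste0(rep(c("X", "Y", "Z"), m),
                               rep(seq_len(m), each = 3))), collapse = "\t")
  tvec <- (seq_len(n) - 1) / motion$rate
  body <- vapply(seq_len(n), function(i) {
    vals <- as.vector(motion$positions[i, , ])  # x,y,z per marker in order
    paste(c(i, format(tvec[i], trim = TRUE),
            formatC(vals, format = "f", digits = digits)), collapse = "\t")
  }, character(1))
  writeLines(c(l1, l2, l3, l4, l5, body), path)
  invisible(path)
}

#' Standing calibration of marker clusters
#'
#' Records, from a single standing frame, the reference configuration of the
#' pelvis and thigh marker clusters together with the anatomical frames and
#' the head/acetabulum centre-to-centre distance. Subsequent motion frames
#' are related to this calibration by least-squares rigid cluster fits.
#'
#' @param standing a [marker_trajectories()] with at least one frame (frame
#'   `frame` is used), or a named `m x 3` matrix of one frame's markers.
#' @param pelvis_frame,femur_frame [anatomical_frame()]s in the standing
#'   posture.
#' @param pelvis_markers,thigh_markers character vectors (>= 3 labels each).
#' @param reference_distance head-to-acetabulum centre distance from the
#'   supine scans (mm, >= 0); default: distance between the two frame
#'   origins.
#' @param frame frame index used for calibration.
#' @return An object of class `hip_calibration`.
#' @export
calibrate_standing <- function(standing, pelvis_frame, femur_frame,
                               pelvis_markers, thigh_markers,
                               reference_distance = NULL, frame = 1L) {
  getm <- function(labels) {
    if (inherits(standing, "marker_trajectories")) {
      frame_markers(standing, frame, labels)
    } else {
      miss <- setdiff(labels, rownames(standing))
      if (length(miss)) stop("markers missing from standing frame: ",
                             paste(miss, collapse = ", "), call. = FALSE)
      as.matrix(standing[labels, , drop = FALSE])
    }
  }
  check_cluster <- function(m, body) {
    if (nrow(m) < 3) stop(body, " cluster needs >= 3 markers", call. = FALSE)
    if (anyNA(m)) stop(body, " cluster has gaps in the calibration frame", call. = FALSE)
    sv <- svd(sweep(m, 2, colMeans(m), "-"), nu = 0, nv = 0)$d
    if (sv[2] < 1e-6 * max(sv[1], 1e-300)) {
      stop("degenerate cluster: ", body, " markers are collinear", call. = FALSE)
    }
    m
  }
  pm <- check_cluster(getm(pelvis_markers), "pelvis")
  tm <- check_cluster(getm(thigh_markers), "thigh")
  if (is.null(reference_distance)) {
    reference_distance <- vnorm(pelvis_frame$origin - femur_frame$origin)
  }
  if (reference_distance < 0) stop("reference_distance must be >= 0", call. = FALSE)
  structure(list(pelvis_markers = pm, thigh_markers = tm,
                 pelvis_frame = pelvis_frame, femur_frame = femur_frame,
                 reference_distance = reference_distance),
            class = "hip_calibration")
}

#' @export
print.hip_calibration <- function(x, ...) {
  cat(sprintf("<hip_calibration: %d pelvis + %d thigh markers, reference distance %.2f mm>\n",
              nrow(x$pelvis_markers), nrow(x$thigh_markers), x$reference_distance))
  invisible(x)
}

# Rigid transform of one body's cluster from calibration to frame `i`;
# NULL if fewer than 3 markers are visible.
cluster_pose <- function(motion, i, calib_markers) {
  cur <- frame_markers(motion, i, rownames(calib_markers))
  vis <- stats::complete.cases(cur)
  if (sum(vis) < 3) return(NULL)
  kabsch_fit(calib_markers[vis, , drop = FALSE], cur[vis, , drop = FALSE])
}

#' Hip joint angles for every motion frame
#'
#' For each frame, fits the current pelvis and thigh cluster markers to their
#' calibration configuration (least-squares rigid fit using all visible
#' markers), propagates the anatomical frames with [frame_pose()], and
#' evaluates [grood_suntay_angles()]. Frames with fewer than 3 visible
#' markers in either cluster are reported as gaps (`NA` angles), never
#' interpolated.
#'
#' @param motion a [marker_trajectories()] containing the calibration labels.
#' @param calib a [calibrate_standing()] result.
#' @param side `"right"` or `"left"`.
#' @return A data frame with columns `frame`, `time`, `flexion`, `adduction`,
#'   `internal_rotation`, `gap`; attribute `"transforms"` holds the per-frame
#'   list of `list(pelvis =, femur =)` [rigid_transform()]s (NULL on gaps)
#'   and attribute `"side"` the side.
#' @export
angles_per_frame <- function(motion, calib, side = c("right", "left")) {
  side <- match.arg(side)
  miss <- setdiff(c(rownames(calib$pelvis_markers), rownames(calib$thigh_markers)),
                  motion$labels)
  if (length(miss)) {
    stop("calibration markers absent from motion data: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  n <- motion$n_frames
  out <- data.frame(frame = seq_len(n), time = (seq_len(n) - 1) / motion$rate,
                    flexion = NA_real_, adduction = NA_real_,
                    internal_rotation = NA_real_, gap = TRUE)
  transforms <- vector("list", n)
  for (i in seq_len(n)) {
    tp <- cluster_pose(motion, i, calib$pelvis_markers)
    tf <- cluster_pose(motion, i, calib$thigh_markers)
    if (is.null(tp) || is.null(tf)) next
    pel <- frame_pose(calib$pelvis_frame, tp)
    fem <- frame_pose(calib$femur_frame, tf)
    ang <- suppressWarnings(grood_suntay_angles(pel, fem, side = side))
    out$flexion[i] <- ang[["flexion"]]
    out$adduction[i] <- ang[["adduction"]]
    out$internal_rotation[i] <- ang[["internal_rotation"]]
    out$gap[i] <- FALSE
    transforms[[i]] <- list(pelvis = tp, femur = tf)
  }
  attr(out, "transforms") <- transforms
  attr(out, "side") <- side
  out
}

#' Match a target posture to the best motion frame
#'
#' Returns the frame whose angle triple minimises the least-squares error
#' ([lsqe()]) against the target; ties are broken by the earliest frame
#' index. Gap frames are skipped.
#'
#' @param motion_angles data frame from [angles_per_frame()] (or any data
#'   frame with `flexion`, `adduction`, `internal_rotation` and optional
#'   `gap`).
#' @param target a [hip_angles()] object or numeric triple (flexion,
#'   adduction, internal rotation in degrees).
#' @return A list with `frame_index` and `lsqe` (degrees).
#' @export
match_frame <- function(motion_angles, target) {
  tgt <- as.numeric(target)[1:3]
  valid <- if ("gap" %in% names(motion_angles)) !motion_angles$gap else
    rep(TRUE, nrow(motion_angles))
  valid <- valid & stats::complete.cases(
    motion_angles[, c("flexion", "adduction", "internal_rotation")])
  if (!any(valid)) stop("no valid (non-gap) frames to match", call. = FALSE)
  d <- sqrt((motion_angles$flexion - tgt[1])^2 +
              (motion_angles$adduction - tgt[2])^2 +
              (motion_angles$internal_rotation - tgt[3])^2)
  d[!valid] <- Inf
  i <- which.min(d)   # which.min returns the earliest index on ties
  list(frame_index = motion_angles$frame[i], lsqe = d[i])
}
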