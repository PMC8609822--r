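#' Construct a point cloud
#'
#' A point cloud is the universal geometry carrier of the package: an ordered
#' set of 3D bone-surface points in millimetres, with a free-text label
#' (e.g. `"femur"`, `"acetabulum"`).
#'
#' @param points numeric matrix with 3 columns (x, y, z in mm), or an object
#'   coercible to one.
#' @param label free-text label carried through transformations.
#' @return An object of class `point_cloud`: a numeric `n x 3` matrix with a
#'   `label` attribute.
#' @examples
#' pc <- point_cloud(matrix(rnorm(30), ncol = 3), label = "femur")
#' nrow(pc)
#' @export
point_cloud <- function(points, label = "") {
  pts <- as.matrix(points)
  if (is.null(dim(pts)) || ncol(pts) != 3) {
    stop("points must be an n x 3 matrix", call. = FALSE)
  }
  storage.mode(pts) <- "double"
  stopifnot_finite(pts, "point cloud")
  dimnames(pts) <- list(NULL, c("x", "y", "z"))
  structure(pts, label = as.character(label)[1], class = c("point_cloud", "matrix", "array"))
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud '%s': %d points>\n", attr(x, "label"), nrow(x)))
  if (nrow(x)) {
    rng <- apply(x, 2, range)
    cat(sprintf("  extent x [%.2f, %.2f]  y [%.2f, %.2f]  z [%.2f, %.2f] mm\n",
                rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  }
  invisible(x)
}

cloud_label <- function(cloud) {
  lb <- attr(cloud, "label")
  if (is.null(lb)) "" else lb
}

as_cloud_matrix <- function(cloud) {
  m <- unclass(cloud)
  attr(m, "label") <- NULL
  m
}

#' Read a point cloud from disk
#'
#' Supports ASCII PLY (`.ply`), ASCII STL (`.stl`; facet vertices are used as
#' the cloud, duplicates removed), and whitespace-separated XYZ (`.xyz`,
#' `.txt`). Format is chosen by file extension unless `format` is given.
#'
#' @param path file path.
#' @param format one of `"ply"`, `"stl"`, `"xyz"` or `NULL` (infer from
#'   extension).
#' @param label cloud label; defaults to the file base name.
#' @return A [point_cloud()].
#' @export
read_point_cloud <- function(path, format = NULL, label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(format)) {
    format <- tolower(tools::file_ext(path))
    if (format %in% c("txt", "pts")) format <- "xyz"
  }
  if (is.null(label)) label <- tools::file_path_sans_ext(basename(path))
  pts <- switch(format,
    ply = read_ply_vertices(path),
    stl = read_stl_vertices(path),
    xyz = {
      m <- as.matrix(utils::read.table(path, header = FALSE))
      if (ncol(m) < 3) stop("XYZ file ", path, ": expected >= 3 columns", call. = FALSE)
      m[, 1:3, drop = FALSE]
    },
    stop("unsupported point cloud format: ", format, call. = FALSE)
  )
  point_cloud(pts, label = label)
}

read_ply_vertices <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || trimws(lines[1]) != "ply") {
    stop("malformed PLY file ", path, ": missing 'ply' magic on line 1", call. = FALSE)
  }
  end <- match("end_header", trimws(lines))
  if (is.na(end)) stop("malformed PLY file ", path, ": no end_header", call. = FALSE)
  header <- trimws(lines[seq_len(end)])
  if (any(grepl("^format\\s+binary", header))) {
    stop("PLY file ", path, ": only ascii format is supported", call. = FALSE)
  }
  vl <- grep("^element\\s+vertex\\s+\\d+", header, value = TRUE)
  if (!length(vl)) stop("malformed PLY file ", path, ": no vertex element", call. = FALSE)
  nvert <- as.integer(strsplit(vl[1], "\\s+")[[1]][3])
  body <- lines[(end + 1):(end + nvert)]
  m <- do.call(rbind, lapply(body, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]][1:3])))
  if (anyNA(m)) stop("malformed PLY file ", path, ": non-numeric vertex data", call. = FALSE)
  m
}

read_stl_vertices <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vx <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (!length(vx)) stop("malformed ASCII STL file ", path, ": no vertex records", call. = FALSE)
  m <- do.call(rbind, lapply(vx, function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]][2:4])
  }))
  if (anyNA(m)) stop("malformed STL file ", path, ": non-numeric vertex data", call. = FALSE)
  unique(m)
}

#' Write a point cloud to disk
#'
#' @inheritParams read_point_cloud
#' @param cloud a [point_cloud()].
#' @param digits number of significant digits retained in text output.
#' @return `path`, invisibly.
#' @export
write_point_cloud <- function(cloud, path, format = NULL, digits = 6) {
  if (is.null(format)) {
    format <- tolower(tools::file_ext(path))
    if (format %in% c("txt", "pts")) format <- "xyz"
  }
  m <- signif(as_cloud_matrix(cloud), digits)
  switch(format,
    ply = {
      hdr <- c("ply", "format ascii 1.0",
               sprintf("comment label %s", cloud_label(cloud)),
               sprintf("element vertex %d", nrow(m)),
               "property float x", "property float y", "property float z",
               "end_header")
      writeLines(c(hdr, apply(m, 1, paste, collapse = " ")), path)
    },
    xyz = utils::write.table(m, path, row.names = FALSE, col.names = FALSE),
    stop("unsupported output format: ", format, call. = FALSE)
  )
  invisible(path)
}

#' Read or write anatomical landmarks
#'
#' Landmarks are named 3-vectors in mm. JSON files store `{name: [x,y,z]}`;
#' CSV files have columns `name,x,y,z`.
#'
#' @param path file path (`.json` or `.csv`).
#' @return A named list of numeric 3-vectors.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  lms <- if (ext == "json") {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    lapply(raw, as.numeric)
  } else if (ext == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("name", "x", "y", "z")
    if (!all(need %in% names(df))) {
      stop("landmark CSV ", path, ": needs columns name,x,y,z", call. = FALSE)
    }
    stats::setNames(lapply(seq_len(nrow(df)), function(i) as.numeric(df[i, c("x", "y", "z")])),
                    df$name)
  } else stop("unsupported landmark format: ", ext, call. = FALSE)
  for (nm in names(lms)) {
    if (length(lms[[nm]]) != 3 || !all(is.finite(lms[[nm]]))) {
      stop("landmark '", nm, "' in ", path, " is not a finite 3-vector", call. = FALSE)
    }
  }
  lms
}

#' @rdname read_landmarks
#' @param landmarks named list of 3-vectors.
#' @export
write_landmarks <- function(landmarks, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(lapply(landmarks, unname), path, digits = 10, auto_unbox = FALSE)
  } else if (ext == "csv") {
    df <- data.frame(name = names(landmarks),
                     t(vapply(landmarks, as.numeric, numeric(3))))
    names(df) <- c("name", "x", "y", "z")
    utils::write.csv(df, path, row.names = FALSE)
  } else stop("unsupported landmark format: ", ext, call. = FALSE)
  invisible(path)
}
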