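# Point-to-point iterative closest point registration.

# Nearest neighbour indices of each row of `query` among rows of `ref`,
# chunked brute force (no spatial-index dependency; adequate for bone clouds
# of a few thousand points).
nearest_neighbours <- function(query, ref, chunk = 512L) {
  nq <- nrow(query)
  idx <- integer(nq); d2 <- numeric(nq)
  rr <- rowSums(ref^2)
  for (s in seq(1L, nq, by = chunk)) {
    e <- min(s + chunk - 1L, nq)
    q <- query[s:e, , drop = FALSE]
    D <- outer(rowSums(q^2), rr, "+") - 2 * tcrossprod(q, ref)
    j <- max.col(-D, ties.method = "first")
    idx[s:e] <- j
    d2[s:e] <- D[cbind(seq_len(nrow(q)), j)]
  }
  list(index = idx, dist = sqrt(pmax(d2, 0)))
}

# Least-squares rigid fit (Kabsch/Umeyama without scale): transform mapping
# rows of A onto rows of B, with SVD reflection guard.
kabsch_fit <- function(A, B, weights = NULL) {
  if (nrow(A) != nrow(B)) stop("point sets differ in size", call. = FALSE)
  if (nrow(A) < 3) stop("rigid fit needs at least 3 points", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, nrow(A))
  w <- weights / sum(weights)
  ca <- colSums(A * w); cb <- colSums(B * w)
  Ac <- sweep(A, 2, ca, "-"); Bc <- sweep(B, 2, cb, "-")
  H <- crossprod(Ac * w, Bc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid_transform(R, cb - as.numeric(R %*% ca))
}

#' Rigid registration by iterative closest point
#'
#' Point-to-point ICP: alternates nearest-neighbour correspondence with the
#' closed-form least-squares rigid update (SVD with reflection guard) until
#' the change in RMS correspondence distance falls below `tol` or `max_iter`
#' is reached. Returns the transform mapping `source` into the `target`
#' frame.
#'
#' @param source,target [point_cloud()]s with at least 10 points each.
#' @param max_iter maximum iterations (>= 1).
#' @param tol convergence tolerance on the RMS change (mm).
#' @param init optional initial [rigid_transform()] applied to `source`
#'   before iterating (default identity). For large posture changes,
#'   pre-align with [landmark_transform()].
#' @param trim_fraction optional worst-fraction trimming in `[0, 0.5)`:
#'   this fraction of the worst correspondences is ignored in each update
#'   (default 0, i.e. the plain algorithm).
#' @return An object of class `icp_result`: `transform`, `rms` (mm, final RMS
#'   correspondence distance), `iterations`, `converged`, `rms_history`.
#' @export
icp_register <- function(source, target, max_iter = 200L, tol = 1e-4,
                         init = NULL, trim_fraction = 0) {
  S <- if (inherits(source, "point_cloud")) as_cloud_matrix(source) else as.matrix(source)
  T_ <- if (inherits(target, "point_cloud")) as_cloud_matrix(target) else as.matrix(target)
  if (nrow(S) < 10 || nrow(T_) < 10) {
    stop("ICP needs at least 10 points in both clouds", call. = FALSE)
  }
  if (tol <= 0) stop("tol must be > 0", call. = FALSE)
  if (trim_fraction < 0 || trim_fraction >= 0.5) {
    stop("trim_fraction must be in [0, 0.5)", call. = FALSE)
  }
  cur <- if (is.null(init)) rigid_transform() else init
  moved <- apply_transform(S, cur)
  prev_rms <- Inf
  history <- numeric(0)
  converged <- FALSE
  iterations <- 0L
  n_keep <- max(3L, floor(nrow(S) * (1 - trim_fraction)))
  for (it in seq_len(max_iter)) {
    iterations <- it
    nn <- nearest_neighbours(moved, T_)
    keep <- if (n_keep < nrow(S)) order(nn$dist)[seq_len(n_keep)] else seq_len(nrow(S))
    rms <- sqrt(mean(nn$dist[keep]^2))
    history <- c(history, rms)
    upd <- kabsch_fit(moved[keep, , drop = FALSE],
                      T_[nn$index[keep], , drop = FALSE])
    cur <- compose_transform(upd, cur)
    moved <- apply_transform(S, cur)
    if (abs(prev_rms - rms) < tol) { converged <- TRUE; break }
    prev_rms <- rms
  }
  nn <- nearest_neighbours(moved, T_)
  keep <- if (n_keep < nrow(S)) order(nn$dist)[seq_len(n_keep)] else seq_len(nrow(S))
  structure(list(transform = cur,
                 rms = sqrt(mean(nn$dist[keep]^2)),
                 iterations = iterations,
                 converged = converged,
                 rms_history = history),
            class = "icp_result")
}

#' @export
print.icp_result <- function(x, ...) {
  cat(sprintf("<icp_result: rms %.5f mm after %d iterations (%s)>\n",
              x$rms, x$iterations,
              if (x$converged) "converged" else "max_iter reached"))
  print(x$transform)
  invisible(x)
}

#' Rigid transform from landmark correspondences
#'
#' Least-squares rigid fit taking named landmarks in one posture onto the
#' same names in another; useful to pre-align before [icp_register()] when
#' the posture change is large.
#'
#' @param from,to named lists of 3-vectors sharing at least 3 names.
#' @return A [rigid_transform()].
#' @export
landmark_transform <- function(from, to) {
  common <- intersect(names(from), names(to))
  if (length(common) < 3) stop("need at least 3 shared landmark names", call. = FALSE)
  A <- do.call(rbind, lapply(from[common], as.numeric))
  B <- do.call(rbind, lapply(to[common], as.numeric))
  kabsch_fit(A, B)
}
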