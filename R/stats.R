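#' Least-squares error between two hip angle triples
#'
#' Euclidean norm of the three angle differences,
#' `sqrt(dFlex^2 + dAdd^2 + dIR^2)`, in degrees. This is the quantity used to
#' match a statically imaged posture to the closest motion frame and to rank
#' participants for threshold inclusion. It is a metric on angle triples:
#' non-negative, symmetric, zero iff the triples are equal, and satisfies the
#' triangle inequality.
#'
#' @param a,b [hip_angles()] objects or numeric triples (flexion, adduction,
#'   internal rotation, degrees). The sign convention must match (same side).
#' @return LSQE in degrees.
#' @examples
#' lsqe(c(84.9, 4.5, 5.4), c(87.9, 3.2, 2.4))
#' @export
lsqe <- function(a, b) {
  if (inherits(a, "hip_angles") && inherits(b, "hip_angles") &&
      !identical(attr(a, "side"), attr(b, "side"))) {
    stop("LSQE compares angles of the same side", call. = FALSE)
  }
  a <- as.numeric(a)[1:3]; b <- as.numeric(b)[1:3]
  stopifnot_finite(c(a, b), "angles")
  sqrt(sum((a - b)^2))
}

#' Model accuracy summary
#'
#' Per-subject absolute errors between model-predicted and directly measured
#' beta angles, summarised as mean, sample SD (n-1 denominator) and RMSE
#' (`sqrt(mean(error^2))`).
#'
#' @param beta_model,beta_reference numeric vectors (degrees), or a 2-column
#'   matrix/data frame passed as `beta_model`.
#' @param ids optional subject identifiers.
#' @return Object of class `accuracy_summary`: `n`, `mean_abs_error`, `sd`,
#'   `rmse` (degrees) and `per_subject` (data frame with `id`, `beta_model`,
#'   `beta_reference`, `abs_error`).
#' @export
accuracy_summary <- function(beta_model, beta_reference = NULL, ids = NULL) {
  if (is.null(beta_reference)) {
    m <- as.matrix(beta_model)
    if (ncol(m) != 2) stop("expected a 2-column matrix of (model, reference) pairs",
                           call. = FALSE)
    beta_reference <- m[, 2]; beta_model <- m[, 1]
  }
  x <- as.numeric(beta_model); y <- as.numeric(beta_reference)
  if (!length(x) || length(x) != length(y)) {
    stop("need n >= 1 paired beta values", call. = FALSE)
  }
  stopifnot_finite(c(x, y), "beta angles")
  if (is.null(ids)) ids <- seq_along(x)
  err <- abs(x - y)
  structure(list(
    n = length(err),
    mean_abs_error = mean(err),
    sd = if (length(err) > 1) stats::sd(err) else 0,
    rmse = sqrt(mean(err^2)),
    per_subject = data.frame(id = ids, beta_model = x, beta_reference = y,
                             abs_error = err)),
    class = "accuracy_summary")
}

#' @export
print.accuracy_summary <- function(x, digits = 1, ...) {
  cat(sprintf("<accuracy_summary: n = %d, mean |error| %.*f (SD %.*f), RMSE %.*f deg>\n",
              x$n, digits, x$mean_abs_error, digits, x$sd, digits, x$rmse))
  invisible(x)
}

#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation; the p-value comes from
#' `t = r sqrt((n-2) / (1-r^2))` against the t distribution with n-2 degrees
#' of freedom (two-sided), via [stats::cor.test()].
#'
#' @param x,y numeric vectors, n >= 3, each with nonzero variance.
#' @return A list with `r`, `p` and `n`.
#' @export
pearson_r <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 3) {
    stop("pearson_r needs paired vectors with n >= 3", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: zero variance in x or y", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Intraclass correlation, absolute agreement
#'
#' ICC(A,1): two-way model, single measures, absolute agreement (McGraw &
#' Wong), treating the paired vectors as two raters scoring n subjects.
#' Computed from the two-way ANOVA mean squares:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)` with k = 2.
#' Absolute agreement penalises a constant offset between the raters, so a
#' shifted copy of `x` scores far below its Pearson correlation.
#'
#' @param x,y numeric vectors, n >= 3.
#' @return ICC coefficient (<= 1).
#' @export
icc_agreement <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n || n < 3) stop("icc_agreement needs paired vectors with n >= 3",
                                    call. = FALSE)
  scores <- cbind(x, y)
  k <- 2
  grand <- mean(scores)
  row_means <- rowMeans(scores)
  col_means <- colMeans(scores)
  ssr <- k * sum((row_means - grand)^2)
  ssc <- n * sum((col_means - grand)^2)
  sse <- sum((scores - outer(row_means, rep(1, k)) -
                outer(rep(1, n), col_means) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (abs(denom) < 1e-15) {
    stop("undefined ICC: degenerate variance structure", call. = FALSE)
  }
  (msr - mse) / denom
}

#' Threshold inclusion by least-squares angle error
#'
#' Implements the inclusion rule used to make final model accuracy
#' independent of posture-match quality: records are sorted by ascending
#' LSQE, and the largest prefix (of size >= 3) is retained whose Pearson
#' correlation between LSQE and absolute beta error is not statistically
#' significant (p >= alpha). If even the full set is non-significant, the
#' full set is returned. If no prefix of size >= 3 qualifies, the smallest
#' prefix is returned with `significant = TRUE`. An undefined correlation
#' (zero variance, e.g. identical errors) counts as non-significant.
#'
#' @param records data frame with columns `id`, `lsqe`, `abs_error` (or a
#'   3-column matrix in that order); n >= 3.
#' @param alpha significance level (default 0.05).
#' @return Object of class `inclusion_result`: `included_ids` (ascending
#'   LSQE), `threshold_rank` (number included), `lsqe_threshold` (largest
#'   included LSQE), `r`, `p`, `icc` for the included set, `significant`.
#' @export
threshold_inclusion <- function(records, alpha = 0.05) {
  df <- as.data.frame(records)
  if (!all(c("id", "lsqe", "abs_error") %in% names(df))) {
    names(df)[1:3] <- c("id", "lsqe", "abs_error")
  }
  if (nrow(df) < 3) stop("threshold inclusion needs >= 3 records", call. = FALSE)
  df <- df[order(df$lsqe), , drop = FALSE]
  test_prefix <- function(m) {
    sub <- df[seq_len(m), , drop = FALSE]
    res <- tryCatch(pearson_r(sub$lsqe, sub$abs_error),
                    error = function(e) list(r = NA_real_, p = 1, n = m))
    res
  }
  chosen <- NULL
  for (m in seq(nrow(df), 3)) {
    res <- test_prefix(m)
    if (res$p >= alpha) { chosen <- list(m = m, res = res, significant = FALSE); break }
  }
  if (is.null(chosen)) chosen <- list(m = 3L, res = test_prefix(3L), significant = TRUE)
  sub <- df[seq_len(chosen$m), , drop = FALSE]
  icc <- tryCatch(icc_agreement(sub$lsqe, sub$abs_error),
                  error = function(e) NA_real_)
  structure(list(included_ids = sub$id,
                 threshold_rank = chosen$m,
                 lsqe_threshold = max(sub$lsqe),
                 r = chosen$res$r, p = chosen$res$p, icc = icc,
                 significant = chosen$significant),
            class = "inclusion_result")
}

#' @export
print.inclusion_result <- function(x, ...) {
  cat(sprintf("<inclusion_result: %d included (LSQE <= %.1f deg), r = %.2f, p = %.2f%s>\n",
              x$threshold_rank, x$lsqe_threshold, x$r, x$p,
              if (x$significant) " [still significant at the smallest prefix]" else ""))
  invisible(x)
}

#' Published squat and FADIR validation tables
#'
#' The printed per-participant validation records for the squatting and
#' sitting-FADIR postures: hip angle triples measured in the upright open-MRI
#' scanner and in the motion lab, the least-squares angle error between them,
#' the beta angles from both systems, their absolute difference, and BMI.
#' These are the inputs for the table-reproduction checks; angles in degrees.
#'
#' @param maneuver `"squat"` or `"fadir"`.
#' @return A data frame with columns `participant`, `flex_molab`,
#'   `flex_openmri`, `ir_molab`, `ir_openmri`, `abd_molab`, `abd_openmri`,
#'   `lsqe`, `beta_molab`, `beta_openmri`, `abs_diff_beta`, `bmi`.
#' @export
validation_table <- function(maneuver = c("squat", "fadir")) {
  maneuver <- match.arg(maneuver)
  path <- system.file("extdata",
                      paste0(maneuver, "_validation.csv"),
                      package = "hipclear", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
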