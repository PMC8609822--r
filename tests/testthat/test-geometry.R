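# Geometry primitives: sphere fitting, plane slicing, projection, axis fit.

cross_oracle <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

test_that("sphere fit is exact on noiseless spherical samples", {
  set.seed(1)
  pts <- sphere_points(100, center = c(0, 0, 0), radius = 1)
  fit <- fit_sphere(pts)
  expect_lt(max(abs(fit$center)), 1e-9)
  expect_lt(abs(fit$radius - 1), 1e-9)
  expect_lt(fit$rms_residual, 1e-9)

  # 4 non-coplanar points on a known sphere are recovered exactly
  dirs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(-1, -1, -1) / sqrt(3))
  pts4 <- sweep(5 * dirs, 2, c(1, 2, 3), "+")
  fit4 <- fit_sphere(pts4)
  expect_lt(max(abs(fit4$center - c(1, 2, 3))), 1e-9)
  expect_lt(abs(fit4$radius - 5), 1e-9)
})

test_that("sphere fit on noisy data matches a direct nonlinear LS oracle", {
  set.seed(42)
  truth <- list(center = c(4, -2, 7), radius = 25)
  pts <- sphere_points(500, truth$center, truth$radius) +
    matrix(rnorm(1500, sd = 0.1), ncol = 3)
  fit <- fit_sphere(pts)
  expect_lt(sqrt(sum((fit$center - truth$center)^2)), 0.05)

  # oracle: generic optimiser on the geometric residual sum
  obj <- function(p) {
    d <- sqrt(rowSums(sweep(pts, 2, p[1:3], "-")^2))
    sum((d - p[4])^2)
  }
  oracle <- optim(c(colMeans(pts), 20), obj, method = "BFGS",
                  control = list(reltol = 1e-15, maxit = 1000))
  expect_lt(max(abs(c(fit$center, fit$radius) - oracle$par)), 1e-6)
})

test_that("sphere fit rejects degenerate input and supports exclusion", {
  set.seed(3)
  planar <- cbind(runif(30), runif(30), 0)
  expect_error(fit_sphere(planar), "coplanar")
  expect_error(fit_sphere(matrix(1, 3, 3)), "at least 4")

  # iterative exclusion recovers the dominant sphere despite a local bump
  pts <- sphere_points(2000, radius = 25)
  g0 <- c(sin(0.8), 0, cos(0.8))  # bump centre direction
  delta <- acos(pmin(1, pmax(-1, (pts %*% g0) / 25))) * 180 / pi
  bump <- 3 * exp(-delta^2 / (2 * 12^2))
  bumped <- pts * as.numeric(1 + bump / 25)
  plain <- fit_sphere(bumped)
  robust <- fit_sphere(bumped, exclude_above = 0.5)
  expect_lt(abs(robust$radius - 25), abs(plain$radius - 25))
  expect_lt(sqrt(sum(robust$center^2)), 0.05)
  expect_lt(abs(robust$radius - 25), 0.05)
})

test_that("slice_by_plane matches the brute-force distance test", {
  pl <- hip_plane(c(0, 0, 0), c(0, 0, 1))
  pts <- point_cloud(cbind(1:5, 0, c(-0.6, -0.4, 0, 0.5, 0.7)))
  kept <- slice_by_plane(pts, pl, 0.5)
  expect_equal(as.numeric(kept[, 1]), c(2, 3, 4))  # boundary inclusive

  expect_equal(nrow(slice_by_plane(pts, pl, 1e9)), 5)  # ~infinite slab
  expect_error(slice_by_plane(pts, pl, 0), "> 0")

  set.seed(7)
  cloud <- point_cloud(matrix(rnorm(600, sd = 10), ncol = 3))
  plane <- hip_plane(rnorm(3), rnorm(3))
  got <- slice_by_plane(cloud, plane, 2)
  dists <- apply(cloud, 1, function(p) sum((p - plane$point) * plane$normal))
  expect_equal(unclass(got), unclass(cloud)[abs(dists) <= 2, , drop = FALSE],
               ignore_attr = TRUE)
})

test_that("plane projection is an isometry with an exact round trip", {
  set.seed(11)
  pl <- hip_plane(c(1, 2, 3), c(1, 1, -1))
  n <- pl$normal
  # two in-plane points 3 mm apart
  e <- c(1, -1, 0) / sqrt(2)
  p1 <- pl$point + 0 * e
  p2 <- pl$point + 3 * e
  pr <- project_to_plane(rbind(p1, p2), pl)
  expect_lt(max(abs(pr$out_of_plane)), 1e-12)
  expect_equal(sqrt(sum((pr$coords[1, ] - pr$coords[2, ])^2)), 3,
               tolerance = 1e-12)

  pts <- matrix(rnorm(60, sd = 5), ncol = 3)
  pr2 <- project_to_plane(pts, pl)
  rec <- unproject_from_plane(pr2$coords, pr2)
  feet <- pts - outer(pr2$out_of_plane, n)  # projection feet, independently
  expect_lt(max(abs(rec - feet)), 1e-9)
})

test_that("axis fit recovers dominant directions and flags isotropy", {
  z <- cbind(0, 0, seq(-5, 5, length.out = 20))
  ax <- fit_axis(z, hint = c(0, 0, 1))
  expect_lt(max(abs(ax$direction - c(0, 0, 1))), 1e-12)
  # canonical sign follows the hint
  ax2 <- fit_axis(z, hint = c(0, 0, -1))
  expect_lt(max(abs(ax2$direction - c(0, 0, -1))), 1e-12)

  set.seed(21)
  t <- runif(3000, -50, 50)
  om <- runif(3000, 0, 2 * pi)
  d0 <- c(1, 2, 2) / 3
  perp1 <- c(2, -1, 0) / sqrt(5); perp2 <- cross_oracle(d0, perp1)
  cyl <- outer(t, d0) + 5 * (outer(cos(om), perp1) + outer(sin(om), perp2))
  axc <- fit_axis(cyl, hint = d0)
  ang <- acos(min(1, abs(sum(axc$direction * d0)))) * 180 / pi
  expect_lt(ang, 0.5)

  blob <- sphere_points(500, radius = 10)
  expect_error(fit_axis(blob), "ambiguous")
})

test_that("point cloud IO round-trips PLY, XYZ and landmark files", {
  set.seed(9)
  pc <- point_cloud(matrix(rnorm(90, sd = 30), ncol = 3), label = "femur")
  d <- withr::local_tempdir()
  ply <- file.path(d, "a.ply"); xyz <- file.path(d, "a.xyz")
  write_point_cloud(pc, ply); write_point_cloud(pc, xyz)
  expect_equal(unclass(read_point_cloud(ply)), unclass(pc),
               tolerance = 1e-5, ignore_attr = TRUE)
  expect_equal(unclass(read_point_cloud(xyz)), unclass(pc),
               tolerance = 1e-5, ignore_attr = TRUE)
  expect_error(read_point_cloud(file.path(d, "missing.ply")), "not found")

  lm <- aligned_landmarks()
  js <- file.path(d, "lm.json"); cs <- file.path(d, "lm.csv")
  write_landmarks(lm, js); write_landmarks(lm, cs)
  expect_equal(read_landmarks(js), lapply(lm, as.numeric))
  got <- read_landmarks(cs)
  expect_equal(got[order(names(got))],
               lapply(lm, as.numeric)[order(names(lm))])

  # malformed file is rejected with a useful message
  writeLines(c("ply", "format ascii 1.0", "element vertex 2"), ply)
  expect_error(read_point_cloud(ply), "end_header")
})
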