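annulus_slice <- function(n = 128, r_in = 40, r_out = 55, wavy = 0, k = 6) {
  pr <- matrix(seq_len(n), n, n)
  pc <- matrix(seq_len(n), n, n, byrow = TRUE)
  cen <- (n + 1) / 2
  r <- sqrt((pr - cen)^2 + (pc - cen)^2)
  th <- atan2(pr - cen, pc - cen)
  ri <- r_in + wavy * sin(k * th)
  (r >= ri & r <= r_out) * 1
}

test_that("lumen edge of a binary annulus sits at the inner radius", {
  m <- annulus_slice()
  pts <- detect_lumen_edge(m, 0.5)
  cen <- (128 + 1) / 2
  d <- sqrt((pts[, 1] - cen)^2 + (pts[, 2] - cen)^2)
  expect_true(all(abs(d - 40) <= 1))
  # counter-clockwise: positive signed area
  expect_gt(vesselct:::polygon_area(pts[, 1], pts[, 2]), 0)
})

test_that("a disk without a hole raises a lumen-not-found error", {
  n <- 64
  pr <- matrix(seq_len(n), n, n); pc <- t(pr)
  disk <- (sqrt((pr - 32)^2 + (pc - 32)^2) < 20) * 1
  expect_error(detect_lumen_edge(disk, 0.5, centre_hint = c(32, 32)),
               "lumen not found")
})

test_that("wavy lumen edge follows the generating function within a voxel", {
  m <- annulus_slice(wavy = 3, k = 6)
  pts <- detect_lumen_edge(m, 0.5)
  cen <- (128 + 1) / 2
  th <- atan2(pts[, 2] - cen, pts[, 1] - cen)
  d <- sqrt((pts[, 1] - cen)^2 + (pts[, 2] - cen)^2)
  # generator used (row - cen) as the sine argument's y: recompute likewise
  th_gen <- atan2(pts[, 2] - cen, pts[, 1] - cen)
  expect_true(all(abs(d - (40 + 3 * sin(6 * th_gen))) <= 1))
})

test_that("interpolating spline reproduces exact circle points", {
  th <- seq(0, 2 * pi, length.out = 65)[-65]
  pts <- cbind(50 + 20 * cos(th), 50 + 20 * sin(th))
  sp <- fit_lumen_spline(pts, 0)
  a <- spline_at_arc(sp, seq(0, sp$perimeter, length.out = 500))
  r <- sqrt((a$x - 50)^2 + (a$y - 50)^2)
  expect_lt(max(abs(r - 20)), 0.1)
  expect_equal(sp$perimeter, 2 * pi * 20, tolerance = 0.01)
})

test_that("smoothing suppresses radial noise below the raw deviation", {
  set.seed(3)
  th <- seq(0, 2 * pi, length.out = 181)[-181]
  noise <- rnorm(length(th))
  r <- 40 + noise
  pts <- cbind(100 + r * cos(th), 100 + r * sin(th))
  sp <- fit_lumen_spline(pts, smoothing_parameter = 1)
  a <- spline_at_arc(sp, seq(0, sp$perimeter, length.out = 720))
  fitted_dev <- max(abs(sqrt((a$x - 100)^2 + (a$y - 100)^2) - 40))
  expect_lt(fitted_dev, max(abs(noise)))
})

test_that("too few points are rejected", {
  th <- seq(0, 2 * pi, length.out = 8)[-8]
  pts <- cbind(cos(th), sin(th))
  expect_error(fit_lumen_spline(pts), "at least 8")
})

test_that("outward normals of a circle point away from the centre", {
  th <- seq(0, 2 * pi, length.out = 65)[-65]
  pts <- cbind(50 + 20 * cos(th), 50 + 20 * sin(th))
  sp <- fit_lumen_spline(pts, 0)
  a <- spline_at_arc(sp, seq(0, sp$perimeter, length.out = 36))
  outward <- (a$x - 50) * a$nx + (a$y - 50) * a$ny
  expect_true(all(outward > 0))
  expect_equal(mean(a$kappa), 1 / 20, tolerance = 0.01)
})
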