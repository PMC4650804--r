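circle_spline <- function(cx = 128, cy = 128, r = 40) {
  th <- seq(0, 2 * pi, length.out = 129)[-129]
  fit_lumen_spline(cbind(cx + r * cos(th), cy + r * sin(th)), 0)
}

test_that("an annulus unwraps to a constant column band", {
  n <- 256
  pr <- matrix(seq_len(n), n, n); pc <- t(pr)
  r <- sqrt((pr - 128)^2 + (pc - 128)^2)
  slice <- (r >= 40 & r < 52) * 100
  sp <- circle_spline()
  uw <- unwrap_slice(slice, sp, n_arc_samples = 200, inner_margin_vox = 5,
                     outer_depth_vox = 30)
  img <- uw$image
  # wall occupies cols [margin+1, margin+12) in every row
  wall_cols <- img[, 7:16]
  expect_true(all(wall_cols > 50))
  expect_true(all(img[, 1:4] < 50))      # inside lumen
  expect_true(all(img[, 20:35] < 50))    # beyond wall
})

test_that("default arc sampling spaces rows about one voxel apart", {
  sp <- circle_spline()
  uw <- unwrap_slice(matrix(0, 256, 256), sp)
  expect_equal(uw$transform$n_arc, ceiling(sp$perimeter))
  expect_equal(sp$perimeter / uw$transform$n_arc, 1, tolerance = 0.01)
})

test_that("zero radial offset rewraps onto the spline", {
  sp <- circle_spline()
  uw <- unwrap_slice(matrix(0, 256, 256), sp, n_arc_samples = 100)
  tr <- uw$transform
  pts <- rewrap_points(cbind(seq_len(100), rep(6, 100)), tr)
  r <- sqrt((pts$x - 128)^2 + (pts$y - 128)^2)
  expect_lt(max(abs(r - 40)), 0.1)
})

test_that("unwrap then rewrap is a sub-half-voxel round trip", {
  for (wavy in c(0, 3)) {
    th <- seq(0, 2 * pi, length.out = 257)[-257]
    r <- 40 + wavy * sin(6 * th)
    sp <- fit_lumen_spline(cbind(128 + r * cos(th), 128 + r * sin(th)), 0)
    uw <- unwrap_slice(matrix(0, 256, 256), sp, n_arc_samples = 256,
                       inner_margin_vox = 5, outer_depth_vox = 40)
    tr <- uw$transform
    rows <- rep(seq(1, 256, by = 8), times = 5)
    cols <- rep(c(2, 8, 14, 20, 26), each = 32)   # within the wall band
    xy <- rewrap_points(cbind(rows, cols), tr)
    back <- unwrap_points(cbind(xy$x, xy$y), tr)
    err <- sqrt(((back$row - rows) * tr$perimeter / tr$n_arc)^2 +
                  (back$col - cols)^2)
    expect_lt(mean(err), 0.5)
  }
})

test_that("out-of-frame points are rejected with their indices", {
  sp <- circle_spline()
  tr <- unwrap_slice(matrix(0, 256, 256), sp, n_arc_samples = 50)$transform
  expect_error(rewrap_points(cbind(c(1, -2), c(5, 5)), tr), "indices: 2")
  expect_error(rewrap_points(cbind(10, 1e4), tr), "outside")
})

test_that("unwrapping approximately preserves wall area for circles", {
  n <- 256
  pr <- matrix(seq_len(n), n, n); pc <- t(pr)
  r <- sqrt((pr - 128)^2 + (pc - 128)^2)
  slice <- (r >= 40 & r < 52) * 100
  sp <- circle_spline()
  uw <- unwrap_slice(slice, sp, inner_margin_vox = 5, outer_depth_vox = 30)
  tr <- uw$transform
  # row-wise Jacobian is 1 on the spline; radially it grows as (1 + d*kappa)
  offsets <- seq_len(tr$n_col) - 1 - tr$inner_margin
  jac <- 1 + outer(tr$anchors$kappa, offsets)
  unwrapped_area <- sum((uw$image > 50) * jac) * sp$perimeter / tr$n_arc
  true_area <- pi * (52^2 - 40^2)
  expect_equal(unwrapped_area, true_area, tolerance = 0.05)
  # without the Jacobian the raw pixel count understates the ring area
  raw <- sum(uw$image > 50) * sp$perimeter / tr$n_arc
  expect_lt(raw, true_area)
})
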