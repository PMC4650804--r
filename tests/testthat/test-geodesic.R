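test_that("weight image construction follows the documented precedence", {
  mask <- matrix(FALSE, 12, 10)
  prof <- tibble::tibble(row = 1:12, xe = NA_integer_, missing = TRUE)
  model <- structure(list(dominant_mean = 5, tolerance = 1),
                     class = "edge_model")
  W <- build_weight_image(mask, model, prof)
  expect_true(all(W$weights == 1))
  # a single qualifying row gets exactly one bonus pixel
  prof$xe[4] <- 4L; prof$missing[4] <- FALSE
  W2 <- build_weight_image(mask, model, prof)
  expect_equal(sum(W2$weights == 3), 1L)
  expect_equal(W2$weights[4, 5], 3)
  # in-mask and qualifying: bonus after penalty
  mask[4, 5] <- TRUE
  W3 <- build_weight_image(mask, model, prof)
  expect_equal(W3$weights[4, 5], 1 - 0.5 + 2)
})

test_that("uniform weights give a vertical path at the first column", {
  W <- matrix(1, 10, 6)
  p <- trace_geodesic_boundary(W, lambda = 0.5, d_max = 1)
  expect_true(all(p$col == 1L))
  expect_equal(attr(p, "cost"), 0)
})

test_that("a full-height ridge attracts the whole path", {
  W <- matrix(1, 15, 12); W[, 7] <- 5
  p <- trace_geodesic_boundary(W, lambda = 0.1, d_max = 2)
  expect_true(all(p$col == 7L))
})

test_that("path cost equals exhaustive enumeration on random instances", {
  set.seed(31)
  for (i in 1:30) {
    W <- matrix(runif(8 * 8), 8, 8)
    p <- trace_geodesic_boundary(W, lambda = 0.3, d_max = 1)
    expect_equal(attr(p, "cost"), brute_force_geodesic_cost(W, 0.3, 1),
                 tolerance = 1e-9)
    # the reported cost matches the reported path
    cost <- max(W) - W
    steps <- abs(diff(p$col))
    recomputed <- sum(cost[cbind(p$row, p$col)]) + 0.3 * sum(steps) +
      0.3 * abs(p$col[8] - p$col[1])
    expect_equal(attr(p, "cost"), recomputed, tolerance = 1e-9)
  }
})

test_that("raising lambda never increases total column deviation", {
  set.seed(37)
  for (i in 1:5) {
    W <- matrix(runif(20 * 15), 20, 15)
    devs <- vapply(c(0.01, 0.1, 0.5, 2, 10), function(l) {
      p <- trace_geodesic_boundary(W, lambda = l, d_max = 2)
      sum(abs(diff(p$col))) + abs(p$col[20] - p$col[1])
    }, numeric(1))
    expect_true(all(diff(devs) <= 1e-9))
  }
})

test_that("degenerate inputs are rejected", {
  expect_error(trace_geodesic_boundary(matrix(1, 1, 5), lambda = 1), "2 rows")
  expect_error(trace_geodesic_boundary(matrix(-1, 5, 5), lambda = 1), ">= 0")
  expect_error(trace_geodesic_boundary(matrix(1, 5, 5)), "lambda")
})

test_that("surface smoothing preserves constants and contracts spikes", {
  m <- matrix(40, 60, 6)
  expect_equal(smooth_boundary_surface(m), m, tolerance = 1e-9)
  m[30, 3] <- 50
  sm <- smooth_boundary_surface(m)
  expect_lt(max(sm) - 40, 10)
  expect_gt(max(sm), 40)
})

test_that("sinusoid attenuation matches the kernel frequency response", {
  n <- 120; cycles <- 10
  omega <- 2 * pi * cycles / n
  m <- matrix(40 + 3 * sin(omega * seq_len(n)), n, 1)
  sm <- smooth_boundary_surface(cbind(m, m), sd_row = 3, sd_slice = 0)
  measured <- (max(sm[, 1]) - min(sm[, 1])) / 6
  k <- vesselct:::gaussian_kernel(3)
  h <- (length(k) - 1) / 2
  predicted <- sum(k * cos(omega * (-h:h)))
  expect_equal(measured, predicted, tolerance = 0.05)
})
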