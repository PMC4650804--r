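test_that("Otsu separates a two-level image and matches the naive oracle", {
  img <- matrix(c(rep(40, 50), rep(200, 50)), 10, 10)
  thr <- otsu_threshold(img)
  expect_gt(thr, 40); expect_lt(thr, 200)
  m1 <- threshold_wall(img, "otsu")
  expect_identical(unclass(m1)[, ], img >= thr)
  m2 <- threshold_wall(img, "fixed", manual_value = 100)
  expect_identical(which(m2), which(m1))
  set.seed(7)
  for (i in 1:5) {
    x <- matrix(sample(c(rnorm(30, 10, 2), rnorm(20, 30, 3))), 10, 5)
    expect_equal(otsu_threshold(x), naive_otsu(x), tolerance = 1e-12)
  }
})

test_that("degenerate thresholding inputs raise errors", {
  expect_error(otsu_threshold(matrix(5, 4, 4)), "no bimodality")
  expect_error(threshold_wall(matrix(1:4, 2), "fixed"), "manual_value")
})

test_that("vertical opening keeps aligned bars and kills transverse ones", {
  m <- matrix(FALSE, 30, 30)
  m[5:20, 10] <- TRUE                 # vertical bar, height 16 >= 9
  m[25, 3:20] <- TRUE                 # 1-px-thick horizontal bar
  out <- open_vertical(m, 9)
  expect_identical(which(out[, 10]), 5:20)
  expect_false(any(out[25, ]))
})

test_that("opening equals the erosion-dilation composition bit for bit", {
  set.seed(11)
  for (i in 1:4) {
    m <- matrix(runif(30 * 20) < 0.45, 30, 20)
    out <- open_vertical(m, 5)
    oracle <- naive_dilate_v(naive_erode_v(m, 5), 5)
    expect_identical(unclass(out)[, ], oracle)
    expect_true(all(which(out) %in% which(m)))   # anti-extensive
  }
})

test_that("island removal matches a flood-fill oracle and keeps boundary sizes", {
  m <- matrix(FALSE, 12, 12)
  m[2, 2:4] <- TRUE                    # 3-pixel blob
  expect_false(any(remove_islands(m, 5)))
  m2 <- matrix(FALSE, 12, 12)
  m2[5:6, 5:6] <- TRUE; m2[10, 10] <- TRUE
  out <- remove_islands(m2, 4)         # 4-pixel blob retained at the bound
  expect_identical(sum(out), 4L)
  set.seed(13)
  for (i in 1:3) {
    m3 <- matrix(runif(20 * 20) < 0.3, 20, 20)
    expect_identical(unclass(remove_islands(m3, 5))[, ],
                     flood_fill_filter(m3, 5))
    expect_true(all(which(remove_islands(m3, 5)) %in% which(m3)))
  }
})

test_that("edge profile equals a naive per-row scan and flags empty rows", {
  m <- matrix(TRUE, 5, 8)
  expect_true(all(edge_profile(m)$xe == 8))
  set.seed(17)
  m2 <- matrix(runif(15 * 10) < 0.4, 15, 10)
  m2[4, ] <- FALSE
  prof <- edge_profile(m2)
  naive <- vapply(seq_len(15), function(r)
    if (any(m2[r, ])) max(which(m2[r, ])) else NA_integer_, integer(1))
  expect_identical(prof$xe, naive)
  expect_true(prof$missing[4])
  expect_false(any(prof$missing[-4] & vapply(seq_len(15)[-4], function(r)
    any(m2[r, ]), logical(1))))
  expect_error(edge_profile(matrix(FALSE, 3, 3)), "wall lost")
})
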