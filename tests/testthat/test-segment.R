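seg_cache <- new.env(parent = emptyenv())

small_noiseless_run <- function() {
  if (is.null(seg_cache$run)) {
    ph <- make_vessel_phantom(small_spec(image_shape = c(8L, 192L, 192L),
                                         lumen_radius_vox = 36,
                                         adventitia_thickness_vox = 14))
    seg <- segment_volume(ph$tomogram)
    seg_cache$run <- list(ph = ph, seg = seg)
  }
  seg_cache$run
}

test_that("noiseless phantom layers are recovered with high Dice", {
  run <- small_noiseless_run()
  gt <- run$ph$ground_truth
  seg <- run$seg
  expect_true(all(seg$diagnostics$status == "ok"))
  expect_gte(dice(seg$labels == 2, gt$labels == 2), 0.98)
  expect_gte(dice(seg$labels == 3, gt$labels == 3 | gt$labels == 4), 0.98)
})

test_that("one boundary contour record is emitted per slice", {
  run <- small_noiseless_run()
  expect_identical(sort(unique(run$seg$contours$slice)),
                   seq_len(dim(run$ph$tomogram$values)[3]))
  expect_identical(nrow(run$seg$contours),
                   run$seg$config$n_arc_samples *
                     dim(run$ph$tomogram$values)[3])
})

test_that("labels keep the lumen-media-adventitia ring topology", {
  run <- small_noiseless_run()
  lab <- run$seg$labels
  for (z in c(1, dim(lab)[3])) {
    l <- lab[, , z]
    pr <- matrix(seq_len(nrow(l)), nrow(l), ncol(l))
    pc <- matrix(seq_len(ncol(l)), nrow(l), ncol(l), byrow = TRUE)
    cen <- c(mean(pr[l == 1]), mean(pc[l == 1]))
    r <- sqrt((pr - cen[1])^2 + (pc - cen[2])^2)
    expect_lt(max(r[l == 1]), min(r[l == 3]))        # lumen inside adventitia
    expect_lt(max(r[l == 1]), max(r[l == 2]))        # lumen inside media ring
    expect_lt(max(r[l == 2]), max(r[l == 3]) + 1e-9) # media inside adventitia
    expect_true(all(tabulate(l + 1L, 4L)[2:4] > 0))
  }
})

test_that("a volume with no lumen fails with a lumen error", {
  n <- 96
  pr <- matrix(seq_len(n), n, n); pc <- t(pr)
  disk <- (sqrt((pr - 48)^2 + (pc - 48)^2) < 30) * 100 + 10
  vol <- tomogram(array(disk, c(n, n, 3)), 1)
  expect_error(segment_volume(vol), "every slice")
})

test_that("noisy phantom still recovers the boundary to ~1 voxel", {
  ph <- make_vessel_phantom(small_spec(image_shape = c(8L, 192L, 192L),
                                       lumen_radius_vox = 36,
                                       adventitia_thickness_vox = 14,
                                       noise_sd = 15, seed = 4))
  seg <- segment_volume(ph$tomogram)
  errs <- boundary_radial_errors(seg, ph$ground_truth)
  expect_lte(median(errs, na.rm = TRUE), 2)
  expect_gte(dice(seg$labels == 2, ph$ground_truth$labels == 2), 0.95)
})
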