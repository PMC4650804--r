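morph_cache <- new.env(parent = emptyenv())

morph_run <- function() {
  if (is.null(morph_cache$run)) {
    ph <- make_vessel_phantom(small_spec(image_shape = c(10L, 192L, 192L),
                                         lumen_radius_vox = 36,
                                         adventitia_thickness_vox = 14,
                                         pore_count = 5L,
                                         pore_radius_range_vox = c(2, 3)))
    seg <- segment_volume(ph$tomogram)
    morph_cache$run <- list(ph = ph, seg = seg)
  }
  morph_cache$run
}

test_that("thickness and CSA recover the analytic phantom geometry", {
  run <- morph_run()
  tm <- run$ph$ground_truth$true_metrics
  th <- layer_thickness(run$seg)
  expect_false(any(th$missing))
  expect_equal(mean(th$medial_thickness_um), tm$medial_thickness_um[1],
               tolerance = 0.05)
  expect_equal(mean(th$adventitial_thickness_um),
               tm$adventitial_thickness_um[1], tolerance = 0.05)
  csa <- cross_sectional_area(run$seg)
  # this deliberately small vessel (thin lamellae) carries a little more
  # relative boundary error than the full-size phantom
  expect_equal(csa$lumen_csa_um2, tm$lumen_csa_um2, tolerance = 0.02)
  expect_equal(csa$media_csa_um2, tm$media_csa_um2, tolerance = 0.035)
})

test_that("class areas are conserved exactly on every slice", {
  run <- morph_run()
  csa <- cross_sectional_area(run$seg)
  total <- csa$lumen_csa_um2 + csa$media_csa_um2 + csa$adventitia_csa_um2 +
    csa$pore_csa_um2 + csa$background_csa_um2
  slice_area <- prod(dim(run$seg$labels)[1:2]) * run$seg$voxel_size_um^2
  expect_equal(total, rep(slice_area, nrow(csa)), tolerance = 1e-12)
})

test_that("media CSA is consistent with the thickness ring formula", {
  run <- morph_run()
  csa <- cross_sectional_area(run$seg)
  th <- layer_thickness(run$seg)
  v <- run$seg$voxel_size_um
  r_l <- sqrt(mean(csa$lumen_csa_um2) / pi)
  t_m <- mean(th$medial_thickness_um)
  ring <- pi * ((r_l + t_m)^2 - r_l^2)
  expect_equal(mean(csa$media_csa_um2), ring, tolerance = 0.03)
})

test_that("an empty class reports zero CSA and the axial length rounds", {
  lab <- array(0L, c(6, 6, 450))
  csa <- cross_sectional_area(lab, 0.75)
  expect_true(all(csa$lumen_csa_um2 == 0))
  expect_identical(attr(csa, "axial_length_um"), 338)
  expect_identical(axial_length_um(450, 0.75), 338)
})

test_that("pores are recovered and absent when nothing is sub-paraffin", {
  run <- morph_run()
  pores <- segment_pores(run$ph$tomogram, run$seg)
  gt_comp <- max(vesselct:::cpp_label_components(
    as.vector(run$ph$ground_truth$labels == 4),
    dim(run$ph$ground_truth$labels)))
  expect_identical(pores$count, gt_comp)
  expect_gt(pores$volume_um3, 0)
  expect_true(all(pores$labels[run$seg$labels == 1] == 1))
  # nothing below paraffin -> zero pores
  none <- segment_pores(run$ph$tomogram, run$seg,
                        paraffin_stats = c(-1000, 1))
  expect_identical(none$count, 0L)
  expect_identical(none$volume_um3, 0)
  expect_error(segment_pores(run$ph$tomogram, run$seg, k_sd = 0), "k_sd")
})

test_that("luminal surface maps measure roughness analytically", {
  nz <- 6; n <- 240
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cyl <- purrr::map_dfr(seq_len(nz), function(z)
    tibble::tibble(slice = z, x = 100 + 50 * cos(th), y = 100 + 50 * sin(th)))
  m <- luminal_surface_map(cyl, voxel_size_um = 0.75)
  expect_lt(m$rms_um, 1e-6)
  a <- 2
  rip <- purrr::map_dfr(seq_len(nz), function(z) {
    r <- 50 + a * cos(12 * th)
    tibble::tibble(slice = z, x = 100 + r * cos(th), y = 100 + r * sin(th))
  })
  m2 <- luminal_surface_map(rip, voxel_size_um = 1)
  expect_equal(m2$rms_um, a / sqrt(2), tolerance = 0.02)
  # axis-oriented ripples: circumferential variance >> axial variance
  expect_gt(m2$var_circumferential_um2, 100 * m2$var_axial_um2)
})

test_that("missing slices interpolate only across short gaps", {
  n <- 60
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  mk <- function(z) tibble::tibble(slice = z, x = 50 + 20 * cos(th),
                                   y = 50 + 20 * sin(th))
  ok <- dplyr::bind_rows(lapply(c(1, 2, 4, 5), mk))       # gap of 1
  m <- luminal_surface_map(ok, voxel_size_um = 1)
  expect_identical(ncol(m$radius_um), 5L)
  bad <- dplyr::bind_rows(lapply(c(1, 5, 6), mk))         # gap of 3
  expect_error(luminal_surface_map(bad, voxel_size_um = 1), "consecutive")
})

test_that("group summaries report SEM and a Welch test", {
  set.seed(19)
  a <- tibble::tibble(slice = 1:40, thickness = rnorm(40, 30, 0.5),
                      group = "0 mmHg")
  b <- tibble::tibble(slice = 1:40, thickness = a$thickness + 5,
                      group = "110 mmHg")
  gs <- summarize_groups(dplyr::bind_rows(a, b), metrics = "thickness")
  expect_equal(gs$sem, gs$sd / sqrt(gs$n), tolerance = 1e-12)
  expect_equal(diff(gs$mean), 5, tolerance = 1e-12)
  expect_lt(gs$p_value[1], 1e-10)
  expect_match(attr(gs, "caveat"), "autocorrelated")
  expect_error(summarize_groups(a, metrics = "thickness"), "two groups")
  one <- dplyr::bind_rows(a[1, ], b)
  expect_error(summarize_groups(one, metrics = "thickness"), "at least 2")
})

test_that("null groups rarely reject at the 5% level", {
  set.seed(23)
  p <- replicate(100, {
    d <- tibble::tibble(v = rnorm(30, 30, 1),
                        group = rep(c("a", "b"), each = 15))
    summarize_groups(d, metrics = "v")$p_value[1]
  })
  expect_gte(mean(p > 0.05), 0.9)
})
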