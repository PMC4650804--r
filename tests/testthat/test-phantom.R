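test_that("circular noiseless phantom matches analytic geometry", {
  spec <- small_spec(ripple_amplitude_vox = 0, waviness_amplitude_vox = 0,
                     centre_offset = 0, lumen_radius_vox = 40,
                     image_shape = c(4L, 192L, 192L), psf_sigma_vox = 0.5)
  ph <- make_vessel_phantom(spec)
  tm <- ph$ground_truth$true_metrics
  # analytic circle area, in voxel^2 and in um^2
  expect_equal(tm$lumen_csa_um2[1] / spec$voxel_size_um^2, pi * 40^2,
               tolerance = 1e-6)
  expect_equal(tm$lumen_csa_um2[1], pi * 40^2 * 0.75^2, tolerance = 1e-6)
  # voxel-counted area agrees within the one-voxel perimeter band
  vox_csa <- sum(ph$ground_truth$labels[, , 1] == 1)
  expect_lt(abs(vox_csa - pi * 40^2), 2 * pi * 40)
})

test_that("phantom generation is deterministic for a fixed seed", {
  spec <- small_spec(noise_sd = 8, pore_count = 3L,
                     pore_radius_range_vox = c(1.5, 2),
                     image_shape = c(8L, 160L, 160L))
  a <- make_vessel_phantom(spec)
  b <- make_vessel_phantom(spec)
  expect_identical(a$tomogram$values, b$tomogram$values)
  expect_identical(a$ground_truth$labels, b$ground_truth$labels)
})

test_that("labels partition the volume", {
  ph <- make_vessel_phantom(small_spec(pore_count = 4L,
                                       pore_radius_range_vox = c(1.5, 2),
                                       image_shape = c(8L, 160L, 160L)))
  lab <- ph$ground_truth$labels
  expect_true(all(lab %in% 0:4))
  expect_identical(sum(tabulate(lab + 1L, 5L)), length(lab))
})

test_that("oversized geometry is rejected with a sizing message", {
  expect_error(phantom_spec(image_shape = c(4L, 96L, 96L),
                            lumen_radius_vox = 50),
               "does not fit")
})

test_that("true metrics respond monotonically to geometry", {
  base <- small_spec()
  bigger <- small_spec(lumen_radius_vox = 36)
  expect_gt(make_vessel_phantom(bigger)$ground_truth$true_metrics$lumen_csa_um2[1],
            make_vessel_phantom(base)$ground_truth$true_metrics$lumen_csa_um2[1])
  few <- small_spec(pore_count = 2L, pore_radius_range_vox = c(1.5, 2),
                    image_shape = c(10L, 160L, 160L))
  many <- small_spec(pore_count = 6L, pore_radius_range_vox = c(1.5, 2),
                     image_shape = c(10L, 160L, 160L))
  expect_gte(sum(make_vessel_phantom(many)$ground_truth$labels == 4),
             sum(make_vessel_phantom(few)$ground_truth$labels == 4))
})

test_that("pressurised pair has the constructed contrasts", {
  base <- small_spec(pore_count = 4L, pore_radius_range_vox = c(1.5, 2),
                     image_shape = c(10L, 192L, 192L), lumen_radius_vox = 32)
  pair <- make_pressurised_pair(base, pressure_effect_spec(
    lumen_radius = 1.22, pore_count = 0))
  tu <- pair$unpressurised$ground_truth$true_metrics
  tp <- pair$pressurised$ground_truth$true_metrics
  # lumen factor 1.22 -> CSA ratio (1.22)^2 (ripple term is identical scale)
  expect_equal(tp$lumen_csa_um2[1] / tu$lumen_csa_um2[1], 1.22^2,
               tolerance = 0.01)
  expect_lt(tp$medial_thickness_um[1], tu$medial_thickness_um[1])
  expect_lt(tp$adventitial_thickness_um[1], tu$adventitial_thickness_um[1])
  # pore factor 0 -> no pore voxels at all
  expect_identical(sum(pair$pressurised$ground_truth$labels == 4), 0L)
})

test_that("zero waviness factor degenerates lamellae to perfect circles", {
  base <- small_spec(image_shape = c(6L, 192L, 192L), lumen_radius_vox = 32)
  pair <- make_pressurised_pair(base, pressure_effect_spec(
    waviness_amplitude = 0))
  br <- pair$pressurised$ground_truth$boundary_radius[, 1]
  expect_equal(sd(br), 0, tolerance = 1e-12)
})

test_that("invalid pressurisation directions are rejected", {
  expect_error(pressure_effect_spec(lumen_radius = 0.9), "> 1")
  expect_error(pressure_effect_spec(layer_thickness = 1.2), "\\(0, 1\\)")
  expect_error(pressure_effect_spec(pore_count = 1), "\\[0, 1\\)")
})

test_that("perturb_with_noise honours its contract", {
  vol <- tomogram(array(100, c(110, 100, 100)), 0.75)
  expect_identical(perturb_with_noise(vol, 0)$values, vol$values)
  a <- perturb_with_noise(vol, 10, seed = 5)
  b <- perturb_with_noise(vol, 10, seed = 5)
  expect_identical(a$values, b$values)
  # law of large numbers: sample SD within 2% of nominal on >= 1e6 voxels
  expect_gte(length(a$values), 1e6)
  expect_equal(sd(a$values - vol$values), 10, tolerance = 0.02)
})
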