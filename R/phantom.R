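#' Specify a synthetic vessel phantom
#'
#' Builds the parameter set for [make_vessel_phantom()]. The phantom emulates
#' a paraffin-embedded artery as imaged by absorption microCT: a
#' paraffin-filled lumen and background, a media of bright concentric wavy
#' elastic lamellae separated by cell-rich interlamellar tissue, a disordered
#' fibrous adventitia whose ground matrix is only slightly denser than
#' paraffin, sub-paraffin-density pores inside the adventitia, PSF blur and
#' additive Gaussian noise. Axially oriented luminal ripples reproduce the
#' surface topography seen in unpressurised vessels.
#'
#' @param image_shape integer (slices, rows, cols) voxel counts.
#' @param voxel_size_um isotropic voxel size, micrometres.
#' @param centre_offset amplitude (voxels) of a smooth per-slice drift of the
#'   vessel centre.
#' @param lumen_radius_vox mean lumen radius in voxels.
#' @param ripple_amplitude_vox,ripple_wavelength_vox amplitude and
#'   circumferential wavelength (voxels) of the axis-aligned luminal ripples.
#' @param n_lamellae number of elastic lamellae.
#' @param lamella_thickness_vox,interlamellar_gap_vox lamellar ring thickness
#'   and interlamellar spacing, voxels.
#' @param waviness_amplitude_vox,waviness_period_rad circumferential lamellar
#'   waviness: radius modulation amplitude (voxels) and angular period
#'   (radians); each lamella gets a random phase.
#' @param adventitia_thickness_vox adventitial layer thickness, voxels.
#' @param fibre_density approximate fraction of adventitial voxels painted at
#'   fibre intensity (short random line segments, length 5-15 voxels).
#' @param pore_count number of spherical pores placed uniformly inside the
#'   adventitia (overlapping spheres merge).
#' @param pore_radius_range_vox length-2 range for uniform pore radii.
#' @param intensity_levels named grey values for `air`, `pore`, `paraffin`,
#'   `adventitia_ground`, `interlamellar`, `adventitia_fibre`, `lamella`.
#'   The ordering pore < paraffin < interlamellar is enforced; the
#'   adventitial ground level sits between paraffin and the texture
#'   threshold so that, as in real tissue, the adventitia fragments under a
#'   grey-level threshold while the media stays solid.
#' @param psf_sigma_vox Gaussian point-spread-function SD in voxels.
#' @param noise_sd additive Gaussian noise SD (grey values).
#' @param seed integer RNG seed; phantoms are bit-reproducible.
#' @return A `phantom_spec` object (validated list).
#' @export
phantom_spec <- function(image_shape = c(64L, 256L, 256L),
                         voxel_size_um = 0.75,
                         centre_offset = 0.3,
                         lumen_radius_vox = 55,
                         ripple_amplitude_vox = 2,
                         ripple_wavelength_vox = 25,
                         n_lamellae = 5L,
                         lamella_thickness_vox = 3,
                         interlamellar_gap_vox = 5,
                         waviness_amplitude_vox = 1.5,
                         waviness_period_rad = 2 * pi / 12,
                         adventitia_thickness_vox = 20,
                         fibre_density = 0.25,
                         pore_count = 20L,
                         pore_radius_range_vox = c(3, 5),
                         intensity_levels = c(air = 0, pore = 20, paraffin = 60,
                                              adventitia_ground = 85,
                                              interlamellar = 120,
                                              adventitia_fibre = 170,
                                              lamella = 200),
                         psf_sigma_vox = 0.7,
                         noise_sd = 0,
                         seed = 1L) {
  spec <- list(image_shape = as.integer(image_shape),
               voxel_size_um = voxel_size_um,
               centre_offset = centre_offset,
               lumen_radius_vox = lumen_radius_vox,
               ripple_amplitude_vox = ripple_amplitude_vox,
               ripple_wavelength_vox = ripple_wavelength_vox,
               n_lamellae = as.integer(n_lamellae),
               lamella_thickness_vox = lamella_thickness_vox,
               interlamellar_gap_vox = interlamellar_gap_vox,
               waviness_amplitude_vox = waviness_amplitude_vox,
               waviness_period_rad = waviness_period_rad,
               adventitia_thickness_vox = adventitia_thickness_vox,
               fibre_density = fibre_density,
               pore_count = as.integer(pore_count),
               pore_radius_range_vox = pore_radius_range_vox,
               intensity_levels = intensity_levels,
               psf_sigma_vox = psf_sigma_vox,
               noise_sd = noise_sd,
               seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  stopifnot(length(spec$image_shape) == 3L, all(spec$image_shape >= 1L))
  if (spec$lumen_radius_vox <= 0) stop("lumen_radius_vox must be > 0")
  if (spec$lamella_thickness_vox <= 0 || spec$interlamellar_gap_vox <= 0 ||
      spec$adventitia_thickness_vox <= 0)
    stop("lamella, gap and adventitia thicknesses must be > 0")
  if (spec$noise_sd < 0) stop("noise_sd must be >= 0")
  if (spec$n_lamellae < 1L) stop("need at least one lamella")
  if (spec$ripple_amplitude_vox < 0 || spec$waviness_amplitude_vox < 0)
    stop("ripple and waviness amplitudes must be >= 0")
  if (spec$fibre_density < 0 || spec$fibre_density > 1)
    stop("fibre_density must be in [0, 1]")
  lv <- spec$intensity_levels
  need <- c("pore", "paraffin", "interlamellar", "lamella",
            "adventitia_ground", "adventitia_fibre")
  if (!all(need %in% names(lv)))
    stop("intensity_levels must name: ", paste(need, collapse = ", "))
  if (!(lv["pore"] < lv["paraffin"] && lv["paraffin"] < lv["interlamellar"]))
    stop("intensity ordering pore < paraffin < interlamellar is required")
  if (spec$pore_count >= 1L &&
      spec$image_shape[1] < 2 * max(spec$pore_radius_range_vox) + 3)
    stop("phantom geometry does not fit: too few slices to contain pores of ",
         "the requested radius; add slices or shrink pore_radius_range_vox")
  geom <- phantom_radii(spec)
  half <- (min(spec$image_shape[2:3]) - 1) / 2
  if (geom$r_out + abs(spec$centre_offset) + 5 > half)
    stop(sprintf(paste0("phantom geometry does not fit: outer wall radius ",
                        "%.1f + drift + 5-voxel paraffin margin exceeds the ",
                        "%.1f-voxel half-extent; enlarge image_shape or ",
                        "shrink the vessel"), geom$r_out, half))
  invisible(spec)
}

# Deterministic radial layout derived from a spec (no RNG).
phantom_radii <- function(spec) {
  start <- spec$lumen_radius_vox + spec$ripple_amplitude_vox +
    spec$waviness_amplitude_vox + 0.5
  pitch <- spec$lamella_thickness_vox + spec$interlamellar_gap_vox
  a <- start + (seq_len(spec$n_lamellae) - 1) * pitch
  rb <- a[spec$n_lamellae] + spec$lamella_thickness_vox
  list(lamella_inner = a,
       r_boundary = rb,                       # media/adventitia interface
       r_out = rb + spec$adventitia_thickness_vox)
}

#' Generate a synthetic vessel tomogram with ground truth
#'
#' Renders the phantom described by a [phantom_spec()]: labels and analytic
#' per-slice metrics are computed from the pre-blur geometry (blur and noise
#' are treated as measurement effects, not anatomy), then the grey volume is
#' blurred with a Gaussian PSF and Gaussian noise is added. Bit-identical for
#' a fixed seed.
#'
#' @param spec a [phantom_spec()].
#' @return A list with class `vessel_phantom`:
#' \describe{
#'   \item{tomogram}{[tomogram()] of the blurred, noisy grey volume.}
#'   \item{ground_truth}{list with `labels` (integer array, 0 background,
#'     1 lumen, 2 media, 3 adventitia, 4 pore), `boundary_theta` /
#'     `boundary_radius` (true media-adventitia radius per angle and slice),
#'     `lumen_theta` / `lumen_radius`, `true_metrics` (tibble, one row per
#'     slice), `pore_count`, `pore_volume_um3` (analytic sum of sphere
#'     volumes) and `centres` (per-slice vessel centre).}
#' }
#' @examples
#' ph <- make_vessel_phantom(phantom_spec(
#'   image_shape = c(4, 96, 96), lumen_radius_vox = 20,
#'   ripple_amplitude_vox = 0, waviness_amplitude_vox = 0,
#'   n_lamellae = 2, adventitia_thickness_vox = 8, pore_count = 2,
#'   pore_radius_range_vox = c(2, 3)))
#' ph$ground_truth$true_metrics[1, ]
#' @export
make_vessel_phantom <- function(spec) {
  validate_phantom_spec(spec)
  with_fixed_seed(spec$seed, render_phantom(spec))
}

render_phantom <- function(spec) {
  shp <- spec$image_shape
  nz <- shp[1]; nr <- shp[2]; nc <- shp[3]
  lv <- spec$intensity_levels
  geom <- phantom_radii(spec)
  r0 <- spec$lumen_radius_vox

  # random phases (fixed-seed stream)
  k_rip <- max(1L, round(2 * pi * r0 / spec$ripple_wavelength_vox))
  phi_rip <- runif(1, 0, 2 * pi)
  k_wav <- max(1L, round(2 * pi / spec$waviness_period_rad))
  phi_lam <- runif(spec$n_lamellae, 0, 2 * pi)

  centre0 <- c((nr + 1) / 2, (nc + 1) / 2)
  zfrac <- 2 * pi * (seq_len(nz) - 1) / max(1L, nz)
  centres <- cbind(row = centre0[1] + spec$centre_offset * cos(zfrac),
                   col = centre0[2] + spec$centre_offset * sin(zfrac))

  r_lumen_fun <- function(theta) {
    if (spec$ripple_amplitude_vox == 0) rep(r0, length(theta))
    else r0 + spec$ripple_amplitude_vox * cos(k_rip * theta + phi_rip)
  }
  waviness_fun <- function(theta, i) {
    if (spec$waviness_amplitude_vox == 0) rep(0, length(theta))
    else spec$waviness_amplitude_vox * sin(k_wav * theta + phi_lam[i])
  }
  r_boundary_fun <- function(theta)
    geom$r_boundary + waviness_fun(theta, spec$n_lamellae)

  labels <- array(LABEL_BACKGROUND, c(nr, nc, nz))
  clean <- array(lv[["paraffin"]], c(nr, nc, nz))
  px_col <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  px_row <- matrix(seq_len(nr), nr, nc)

  for (z in seq_len(nz)) {
    dy <- px_row - centres[z, "row"]; dx <- px_col - centres[z, "col"]
    r <- sqrt(dx^2 + dy^2); th <- atan2(dy, dx)
    rl <- r_lumen_fun(th); rb <- r_boundary_fun(th)
    lab <- matrix(LABEL_BACKGROUND, nr, nc)
    lab[r < geom$r_out] <- LABEL_ADVENTITIA
    lab[r < rb] <- LABEL_MEDIA
    lab[r < rl] <- LABEL_LUMEN
    img <- matrix(lv[["paraffin"]], nr, nc)
    img[lab == LABEL_MEDIA] <- lv[["interlamellar"]]
    img[lab == LABEL_ADVENTITIA] <- lv[["adventitia_ground"]]
    for (i in seq_len(spec$n_lamellae)) {
      wi <- waviness_fun(th, i)
      ring <- lab == LABEL_MEDIA & r >= geom$lamella_inner[i] + wi &
        r < geom$lamella_inner[i] + spec$lamella_thickness_vox + wi
      img[ring] <- lv[["lamella"]]
    }
    adv_idx <- which(lab == LABEL_ADVENTITIA)
    if (length(adv_idx) && spec$fibre_density > 0) {
      fib <- draw_fibre_pixels(length(adv_idx) * spec$fibre_density,
                               centres[z, ], geom, nr, nc)
      fib <- fib[lab[fib] == LABEL_ADVENTITIA]
      img[fib] <- lv[["adventitia_fibre"]]
    }
    labels[, , z] <- lab
    clean[, , z] <- img
  }

  pores <- place_pores(spec, geom, centres, nz)
  if (nrow(pores)) {
    for (p in seq_len(nrow(pores))) {
      rp <- pores$radius[p]
      zr <- max(1L, floor(pores$z[p] - rp)):min(nz, ceiling(pores$z[p] + rp))
      for (z in zr) {
        dz <- z - pores$z[p]
        rho <- sqrt(max(0, rp^2 - dz^2))
        if (rho <= 0) next
        rr <- max(1L, floor(pores$row[p] - rho)):min(nr, ceiling(pores$row[p] + rho))
        cc <- max(1L, floor(pores$col[p] - rho)):min(nc, ceiling(pores$col[p] + rho))
        d2 <- outer((rr - pores$row[p])^2, (cc - pores$col[p])^2, `+`)
        inside <- d2 <= rho^2
        sub_lab <- labels[rr, cc, z]
        sel <- inside & sub_lab == LABEL_ADVENTITIA
        sub_lab[sel] <- LABEL_PORE
        labels[rr, cc, z] <- sub_lab
        sub_img <- clean[rr, cc, z]
        sub_img[sel] <- lv[["pore"]]
        clean[rr, cc, z] <- sub_img
      }
    }
  }

  truth_tbl <- phantom_true_metrics(spec, geom, pores, nz,
                                    r_lumen_fun, r_boundary_fun)

  vol <- gaussian_blur3d(clean, spec$psf_sigma_vox)
  if (spec$noise_sd > 0)
    vol <- vol + array(rnorm(length(vol), 0, spec$noise_sd), dim(vol))

  theta_grid <- seq(0, 2 * pi, length.out = 513L)[-513L]
  gt <- list(labels = labels,
             boundary_theta = theta_grid,
             boundary_radius = matrix(r_boundary_fun(theta_grid),
                                      nrow = length(theta_grid), ncol = nz),
             lumen_theta = theta_grid,
             lumen_radius = matrix(r_lumen_fun(theta_grid),
                                   nrow = length(theta_grid), ncol = nz),
             r_out = geom$r_out,
             centres = centres,
             true_metrics = truth_tbl,
             pore_count = nrow(pores),
             pore_table = pores,
             pore_volume_um3 = sum(4 / 3 * pi * pores$radius^3) *
               spec$voxel_size_um^3,
             spec = spec)
  structure(list(tomogram = tomogram(vol, spec$voxel_size_um),
                 ground_truth = gt),
            class = "vessel_phantom")
}

# Random short line segments inside the adventitial annulus; returns linear
# pixel indices (may repeat; caller clips to the adventitia label).
draw_fibre_pixels <- function(target_px, centre, geom, nr, nc) {
  n_seg <- max(1L, ceiling(target_px / 12))
  th <- runif(n_seg, 0, 2 * pi)
  rr <- sqrt(runif(n_seg, geom$r_boundary^2, geom$r_out^2))
  cy <- centre[1] + rr * sin(th); cx <- centre[2] + rr * cos(th)
  ang <- runif(n_seg, 0, pi)
  len <- runif(n_seg, 5, 15)
  u <- rep(seq(-0.5, 0.5, length.out = 40L), times = n_seg)
  y <- round(rep(cy, each = 40L) + u * rep(len * sin(ang), each = 40L))
  x <- round(rep(cx, each = 40L) + u * rep(len * cos(ang), each = 40L))
  keep <- y >= 1 & y <= nr & x >= 1 & x <= nc
  unique((x[keep] - 1L) * nr + y[keep])
}

# Uniform pore placement fully inside the adventitia annulus (no overlap
# testing; overlapping spheres simply merge).
place_pores <- function(spec, geom, centres, nz) {
  n <- spec$pore_count
  if (n < 1L)
    return(tibble::tibble(row = numeric(0), col = numeric(0), z = numeric(0),
                          radius = numeric(0)))
  pr <- runif(n, spec$pore_radius_range_vox[1], spec$pore_radius_range_vox[2])
  lo <- geom$r_boundary + spec$waviness_amplitude_vox + pr + 1
  hi <- geom$r_out - pr - 1
  if (any(hi <= lo))
    stop("adventitia too thin to contain pores of the requested radius")
  th <- runif(n, 0, 2 * pi)
  rad <- sqrt(runif(n, lo^2, hi^2))
  zpos <- runif(n, pr + 1.5, nz - pr - 0.5)
  zc <- pmin(pmax(round(zpos), 1), nz)
  tibble::tibble(row = centres[zc, "row"] + rad * sin(th),
                 col = centres[zc, "col"] + rad * cos(th),
                 z = zpos, radius = pr)
}

# Analytic per-slice metrics from the pre-blur geometry (fine angular
# quadrature; pores assumed non-overlapping for the analytic areas).
phantom_true_metrics <- function(spec, geom, pores, nz,
                                 r_lumen_fun, r_boundary_fun) {
  th <- seq(0, 2 * pi, length.out = 2049L)[-2049L]
  rl <- r_lumen_fun(th); rb <- r_boundary_fun(th)
  dth <- 2 * pi / length(th)
  v2 <- spec$voxel_size_um^2
  lumen_csa <- 0.5 * sum(rl^2) * dth * v2
  media_csa <- 0.5 * sum(rb^2 - rl^2) * dth * v2
  adv_full <- 0.5 * sum(geom$r_out^2 - rb^2) * dth * v2
  med_th <- mean(rb - rl) * spec$voxel_size_um
  adv_th <- mean(geom$r_out - rb) * spec$voxel_size_um
  pore_csa <- vapply(seq_len(nz), function(z) {
    if (!nrow(pores)) return(0)
    dz <- z - pores$z
    rho2 <- pmax(0, pores$radius^2 - dz^2)
    sum(pi * rho2) * v2
  }, numeric(1))
  tibble::tibble(slice = seq_len(nz),
                 lumen_csa_um2 = lumen_csa,
                 media_csa_um2 = media_csa,
                 adventitia_csa_um2 = adv_full - pore_csa,
                 pore_csa_um2 = pore_csa,
                 medial_thickness_um = med_th,
                 adventitial_thickness_um = adv_th)
}

#' Pressurisation effect factors for phantom pairs
#'
#' Multiplicative factors describing intra-luminal pressurisation: the lumen
#' dilates while both wall layers thin, lamellae straighten, luminal ripples
#' flatten and adventitial pores close.
#'
#' @param lumen_radius factor > 1 applied to the lumen radius.
#' @param layer_thickness factor in (0, 1) applied to lamellar thickness,
#'   interlamellar gap and adventitial thickness.
#' @param ripple_amplitude,waviness_amplitude,pore_count factors in `[0, 1)`.
#' @return A validated `pressure_effect_spec` list.
#' @export
pressure_effect_spec <- function(lumen_radius = 1.22,
                                 layer_thickness = 0.85,
                                 ripple_amplitude = 0.4,
                                 waviness_amplitude = 0.4,
                                 pore_count = 0.3) {
  if (lumen_radius <= 1) stop("lumen radius factor must be > 1")
  if (layer_thickness <= 0 || layer_thickness >= 1)
    stop("layer thickness factor must be in (0, 1)")
  for (nm in c("ripple_amplitude", "waviness_amplitude", "pore_count")) {
    v <- get(nm)
    if (v < 0 || v >= 1) stop(nm, " factor must be in [0, 1)")
  }
  structure(list(lumen_radius = lumen_radius,
                 layer_thickness = layer_thickness,
                 ripple_amplitude = ripple_amplitude,
                 waviness_amplitude = waviness_amplitude,
                 pore_count = pore_count),
            class = "pressure_effect_spec")
}

#' Generate an unpressurised / pressurised phantom pair
#'
#' Applies [pressure_effect_spec()] factors to a base [phantom_spec()] so
#' that, by construction, the pressurised member has a larger lumen CSA,
#' thinner media and adventitia, straighter lamellae, a smoother luminal
#' surface and fewer pores than the unpressurised member.
#'
#' @param base_spec [phantom_spec()] for the unpressurised vessel.
#' @param pressurisation a [pressure_effect_spec()].
#' @return list with elements `unpressurised` and `pressurised`, each a
#'   `vessel_phantom` as returned by [make_vessel_phantom()].
#' @export
make_pressurised_pair <- function(base_spec,
                                  pressurisation = pressure_effect_spec()) {
  if (!inherits(pressurisation, "pressure_effect_spec"))
    stop("`pressurisation` must be a pressure_effect_spec")
  p <- pressurisation
  pres <- base_spec
  pres$lumen_radius_vox <- base_spec$lumen_radius_vox * p$lumen_radius
  pres$lamella_thickness_vox <- base_spec$lamella_thickness_vox * p$layer_thickness
  pres$interlamellar_gap_vox <- base_spec$interlamellar_gap_vox * p$layer_thickness
  pres$adventitia_thickness_vox <-
    base_spec$adventitia_thickness_vox * p$layer_thickness
  pres$ripple_amplitude_vox <- base_spec$ripple_amplitude_vox * p$ripple_amplitude
  pres$waviness_amplitude_vox <-
    base_spec$waviness_amplitude_vox * p$waviness_amplitude
  pres$pore_count <- as.integer(floor(base_spec$pore_count * p$pore_count))
  pres$seed <- base_spec$seed + 1000L
  validate_phantom_spec(pres)
  list(unpressurised = make_vessel_phantom(base_spec),
       pressurised = make_vessel_phantom(pres))
}

#' Add Gaussian noise to a tomogram
#'
#' @param vol a [tomogram()].
#' @param noise_sd standard deviation of i.i.d. additive Gaussian noise;
#'   `0` returns the input unchanged.
#' @param seed RNG seed (same seed, same noise field).
#' @return A [tomogram()].
#' @export
perturb_with_noise <- function(vol, noise_sd, seed = 1L) {
  vol <- as_tomogram(vol)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (noise_sd == 0) return(vol)
  vol$values <- vol$values +
    with_fixed_seed(seed,
                    array(rnorm(length(vol$values), 0, noise_sd),
                          dim(vol$values)))
  vol
}

#' @export
print.vessel_phantom <- function(x, ...) {
  d <- dim(x$tomogram$values)
  cat(sprintf("<vessel_phantom> %d x %d x %d voxels, %d pores, seed %d\n",
              d[1], d[2], d[3], x$ground_truth$pore_count,
              x$ground_truth$spec$seed))
  invisible(x)
}
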