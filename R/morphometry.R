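# Quantification of segmented volumes: per-slice thicknesses and
# cross-sectional areas, adventitial pore statistics, luminal-surface
# topography and group comparisons.

#' Per-slice layer thickness
#'
#' Measures layer thickness along the unwrap normals (the radial direction
#' of the unwrapped frame): per row, medial thickness is the distance from
#' the lumen edge (the spline column) to the media-adventitia boundary, and
#' adventitial thickness from the boundary to the outer wall edge; the
#' per-slice value is the mean over rows. Slices that failed segmentation
#' are recorded as missing, not zero.
#'
#' @param seg a [segment_volume()] result.
#' @param voxel_size_um voxel size; defaults to the segmentation's.
#' @return Tibble: `slice`, `medial_thickness_um`,
#'   `adventitial_thickness_um`, `n_rows_used`, `missing`.
#' @export
layer_thickness <- function(seg, voxel_size_um = NULL) {
  stopifnot(inherits(seg, "layer_segmentation"))
  v <- voxel_size_um %||% seg$voxel_size_um
  lumen_col <- seg$config$inner_margin_vox + 1
  nz <- ncol(seg$boundary)
  purrr::map_dfr(seq_len(nz), function(z) {
    b <- seg$boundary[, z]; o <- seg$outer_edge[, z]
    if (all(is.na(b)))
      return(tibble::tibble(slice = z, medial_thickness_um = NA_real_,
                            adventitial_thickness_um = NA_real_,
                            n_rows_used = 0L, missing = TRUE))
    use <- !is.na(b) & !is.na(o)
    tibble::tibble(slice = z,
                   medial_thickness_um = mean(b[use] - lumen_col) * v,
                   adventitial_thickness_um = mean(o[use] - b[use]) * v,
                   n_rows_used = sum(use), missing = FALSE)
  })
}

#' Per-slice cross-sectional areas
#'
#' CSA of each label class per trans-axial slice (voxel count times squared
#' voxel size). The axial length of the stack, slice count times voxel
#' size rounded to the nearest micrometre, is attached as the
#' `axial_length_um` attribute and returned by [axial_length_um()].
#'
#' @param labels integer label array (0 background, 1 lumen, 2 media,
#'   3 adventitia, 4 pore) or a `layer_segmentation`.
#' @param voxel_size_um voxel size in micrometres.
#' @return Tibble: `slice`, `lumen_csa_um2`, `media_csa_um2`,
#'   `adventitia_csa_um2`, `pore_csa_um2`, `background_csa_um2`.
#' @export
cross_sectional_area <- function(labels, voxel_size_um = NULL) {
  if (inherits(labels, "layer_segmentation")) {
    voxel_size_um <- voxel_size_um %||% labels$voxel_size_um
    labels <- labels$labels
  }
  if (is.null(voxel_size_um)) stop("voxel_size_um required")
  v2 <- voxel_size_um^2
  nz <- dim(labels)[3]
  counts <- vapply(seq_len(nz), function(z)
    tabulate(as.vector(labels[, , z]) + 1L, nbins = 5L), integer(5))
  out <- tibble::tibble(slice = seq_len(nz),
                        lumen_csa_um2 = counts[2, ] * v2,
                        media_csa_um2 = counts[3, ] * v2,
                        adventitia_csa_um2 = counts[4, ] * v2,
                        pore_csa_um2 = counts[5, ] * v2,
                        background_csa_um2 = counts[1, ] * v2)
  attr(out, "axial_length_um") <- axial_length_um(nz, voxel_size_um)
  attr(out, "voxel_size_um") <- voxel_size_um
  out
}

#' Axial length of a stack, rounded to the nearest micrometre
#'
#' @param n_slices slice count.
#' @param voxel_size_um voxel size in micrometres.
#' @return Integer-valued length in micrometres (`floor(x + 0.5)` rounding,
#'   so 450 slices at 0.75 um report 338).
#' @export
axial_length_um <- function(n_slices, voxel_size_um) {
  floor(n_slices * voxel_size_um + 0.5)
}

#' Segment adventitial pores
#'
#' Pores are connected regions inside the wall's filled outer hull whose
#' X-ray density falls below the paraffin level: voxels darker than
#' `paraffin mean - k_sd * SD`, grouped into 26-connected components of at
#' least `min_size_vox` voxels. The wall hull is the per-slice morphological
#' closing (disc, radius 5) of the wall mask with interior holes filled.
#'
#' @param vol the grey [tomogram()] (ideally the bilateral-filtered one).
#' @param labels label array or `layer_segmentation` (wall = media +
#'   adventitia).
#' @param paraffin_stats optional `c(mean, sd)` of the paraffin background;
#'   by default estimated (median / MAD) from the background voxels outside
#'   the wall. An error is raised when no background region is available.
#' @param k_sd threshold depth in background SDs (default 3).
#' @param min_size_vox minimum pore component size in voxels.
#' @return A `pore_segmentation`: list with `labels` (pore-augmented array),
#'   `count`, `volume_um3`, `threshold`, and `per_slice` tibble of pore CSA.
#' @export
segment_pores <- function(vol, labels, paraffin_stats = NULL, k_sd = 3,
                          min_size_vox = 9L) {
  vol <- as_tomogram(vol)
  if (inherits(labels, "layer_segmentation")) labels <- labels$labels
  if (k_sd <= 0) stop("k_sd must be > 0")
  v <- vol$values
  if (is.null(paraffin_stats)) {
    bg <- v[labels == LABEL_BACKGROUND]
    if (!length(bg)) stop("no background region available for paraffin statistics")
    paraffin_stats <- c(stats::median(bg), stats::mad(bg))
    if (paraffin_stats[2] == 0)
      paraffin_stats[2] <- max(sd(bg), .Machine$double.eps)
  }
  thr <- paraffin_stats[1] - k_sd * paraffin_stats[2]
  nz <- dim(v)[3]
  brush <- EBImage::makeBrush(11L, shape = "disc")
  hull <- array(FALSE, dim(v))
  for (z in seq_len(nz)) {
    wall <- labels[, , z] %in% c(LABEL_MEDIA, LABEL_ADVENTITIA, LABEL_PORE)
    wall <- matrix(wall, dim(v)[1], dim(v)[2])
    if (!any(wall)) next
    closed <- EBImage::closing(wall + 0, brush)
    hull[, , z] <- EBImage::fillHull(closed) > 0.5
  }
  cand <- hull & v < thr
  out_labels <- labels
  count <- 0L; vol_vox <- 0L
  if (any(cand)) {
    comp <- cpp_label_components(as.vector(cand), dim(v))
    sizes <- tabulate(comp)
    keep_ids <- which(sizes >= min_size_vox)
    count <- length(keep_ids)
    if (count) {
      pore_vox <- comp > 0L & sizes[pmax(comp, 1L)] >= min_size_vox
      vol_vox <- sum(pore_vox)
      out_labels[array(pore_vox, dim(v))] <- LABEL_PORE
    }
  }
  per_slice <- tibble::tibble(
    slice = seq_len(nz),
    pore_csa_um2 = vapply(seq_len(nz), function(z)
      sum(out_labels[, , z] == LABEL_PORE), numeric(1)) * vol$voxel_size_um^2)
  structure(list(labels = out_labels, count = count,
                 volume_um3 = vol_vox * vol$voxel_size_um^3,
                 threshold = thr, paraffin_stats = paraffin_stats,
                 per_slice = per_slice),
            class = "pore_segmentation")
}

#' Luminal surface map and roughness
#'
#' Builds the unwrapped luminal-surface height map: lumen radius (um) per
#' (arc sample, slice) about each slice's contour centroid, the residual
#' map after per-slice mean removal, RMS and mean-absolute roughness, and
#' the directional variance decomposition that distinguishes axis-oriented
#' ripples (circumferential variance much larger than axial variance) from
#' axial corrugation.
#'
#' @param x a `layer_segmentation`, or a tibble with columns `slice`, `x`,
#'   `y` of lumen edge points per slice.
#' @param voxel_size_um voxel size (required for a tibble input).
#' @param n_arc arc samples of the common grid.
#' @param max_gap maximum run of consecutive missing slices to interpolate;
#'   longer gaps raise an error.
#' @return A `surface_map`: list with `theta`, `radius_um` (n_arc x slices),
#'   `residual_um`, `rms_um`, `mean_abs_um`, `var_circumferential_um2`,
#'   `var_axial_um2`.
#' @export
luminal_surface_map <- function(x, voxel_size_um = NULL, n_arc = 360L,
                                max_gap = 2L) {
  theta <- seq(0, 2 * pi, length.out = n_arc + 1L)[-(n_arc + 1L)]
  if (inherits(x, "layer_segmentation")) {
    voxel_size_um <- voxel_size_um %||% x$voxel_size_um
    pts <- x$lumen_contours
    nz <- length(pts)
    rad <- matrix(NA_real_, n_arc, nz)
    for (z in seq_len(nz)) {
      p <- pts[[z]]
      if (is.null(p)) next
      rad[, z] <- radius_on_grid(p[, 1], p[, 2], theta)
    }
  } else {
    if (is.null(voxel_size_um)) stop("voxel_size_um required")
    x <- tibble::as_tibble(x)
    slices <- sort(unique(x$slice))
    nz <- max(slices)
    rad <- matrix(NA_real_, n_arc, nz)
    for (z in slices) {
      p <- x[x$slice == z, ]
      rad[, z] <- radius_on_grid(p$x, p$y, theta)
    }
  }
  if (ncol(rad) < 2L) stop("need lumen contours for at least 2 slices")
  miss <- which(is.na(rad[1, ]))
  if (length(miss)) {
    runs <- rle(seq_len(ncol(rad)) %in% miss)
    if (any(runs$lengths[runs$values] > max_gap))
      stop("more than ", max_gap, " consecutive slices missing; cannot interpolate")
    good <- which(!is.na(rad[1, ]))
    for (r in seq_len(n_arc))
      rad[r, miss] <- approx(good, rad[r, good], xout = miss, rule = 2)$y
  }
  rad_um <- rad * voxel_size_um
  resid <- sweep(rad_um, 2, colMeans(rad_um))
  structure(list(theta = theta, radius_um = rad_um, residual_um = resid,
                 rms_um = sqrt(mean(resid^2)),
                 mean_abs_um = mean(abs(resid)),
                 var_circumferential_um2 = mean(apply(resid, 2, var)),
                 var_axial_um2 = mean(apply(resid, 1, var))),
            class = "surface_map")
}

# Periodic cubic-spline resampling of a closed contour's radius function
# onto a common angle grid (linear interpolation would clip ripple peaks).
radius_on_grid <- function(px, py, theta) {
  cx <- mean(px); cy <- mean(py)
  th <- atan2(py - cy, px - cx)
  r <- sqrt((px - cx)^2 + (py - cy)^2)
  o <- order(th)
  th <- th[o]; r <- r[o]
  keep <- c(TRUE, diff(th) > 1e-9)
  th <- th[keep]; r <- r[keep]
  f <- splinefun(c(th, th[1] + 2 * pi), c(r, r[1]), method = "periodic")
  f(ifelse(theta < th[1], theta + 2 * pi, theta))
}

#' @export
print.surface_map <- function(x, ...) {
  cat(sprintf("<surface_map> %d x %d samples, RMS roughness %.3f um (circ/axial variance ratio %.2f)\n",
              nrow(x$radius_um), ncol(x$radius_um), x$rms_um,
              x$var_circumferential_um2 / max(x$var_axial_um2, 1e-12)))
  invisible(x)
}

#' Assemble the per-slice morphometry table
#'
#' Joins thickness, CSA and pore records into one tidy table, with the
#' stack metadata (voxel size, slice count, axial length) as attributes.
#'
#' @param seg a `layer_segmentation`.
#' @param pores optional [segment_pores()] result; its pore-augmented labels
#'   replace the segmentation labels in the CSA accounting.
#' @return Tibble, one row per slice.
#' @export
morphometry_table <- function(seg, pores = NULL) {
  labels <- if (is.null(pores)) seg$labels else pores$labels
  csa <- cross_sectional_area(labels, seg$voxel_size_um)
  th <- layer_thickness(seg)
  out <- dplyr::left_join(th, csa, by = "slice")
  attr(out, "voxel_size_um") <- seg$voxel_size_um
  attr(out, "n_slices") <- dim(seg$labels)[3]
  attr(out, "axial_length_um") <- axial_length_um(dim(seg$labels)[3],
                                                  seg$voxel_size_um)
  out
}

#' Group summary and two-group comparison
#'
#' Per metric and group: mean, SD and SEM over slices, plus a Welch
#' two-sample t-test between the two groups. Tomographic slices are
#' spatially autocorrelated, so the p-values are anti-conservative; this
#' caveat is attached to the result rather than corrected.
#'
#' @param data tibble with a grouping column and numeric metric columns
#'   (e.g. stacked [morphometry_table()]s with a `group` column).
#' @param group_col name of the grouping column (two groups).
#' @param metrics metric column names; default all numeric columns except
#'   `slice`.
#' @return A `group_summary` tibble: `metric`, `group`, `n`, `mean`, `sd`,
#'   `sem`, and per metric `t_statistic`, `p_value`; attribute `caveat`
#'   documents the autocorrelation warning.
#' @export
summarize_groups <- function(data, group_col = "group", metrics = NULL) {
  data <- tibble::as_tibble(data)
  if (!group_col %in% names(data)) stop("missing grouping column: ", group_col)
  g <- factor(data[[group_col]])
  if (nlevels(g) != 2L) stop("exactly two groups are required")
  if (any(table(g) < 2L)) stop("each group needs at least 2 slices")
  if (is.null(metrics)) {
    metrics <- names(data)[vapply(data, is.numeric, logical(1))]
    metrics <- setdiff(metrics, c("slice", group_col, "n_rows_used"))
  }
  out <- purrr::map_dfr(metrics, function(m) {
    v <- data[[m]]
    keep <- !is.na(v)
    tt <- t.test(v[keep] ~ g[keep])
    per_group <- purrr::map_dfr(levels(g), function(lv) {
      vv <- v[keep & g == lv]
      tibble::tibble(metric = m, group = lv, n = length(vv),
                     mean = mean(vv), sd = sd(vv),
                     sem = sd(vv) / sqrt(length(vv)))
    })
    per_group$t_statistic <- unname(tt$statistic)
    per_group$p_value <- tt$p.value
    per_group
  })
  attr(out, "caveat") <-
    "slices are spatially autocorrelated - p-values anti-conservative"
  class(out) <- c("group_summary", class(out))
  out
}
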