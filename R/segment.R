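# End-to-end per-slice segmentation driver: filter -> lumen spline ->
# unwrap -> threshold -> texture opening -> edge GMM -> geodesic -> 3D
# smoothing -> rewrap -> label volume.

#' Segmentation configuration
#'
#' All tunable stage parameters of [segment_volume()], with defaults. None
#' of the texture/weight magnitudes are canonical; they are exposed here and
#' recorded in the provenance of every run.
#'
#' @param bilateral_window_vox,bilateral_sigma_spatial,bilateral_sigma_range
#'   axial bilateral filter parameters; `NULL` range sigma means a robust
#'   noise estimate.
#' @param spline_smoothing periodic smoothing-spline parameter for the lumen
#'   fit (0 interpolates).
#' @param spline_basis_dim cyclic-basis dimension of the lumen spline; see
#'   [fit_lumen_spline()].
#' @param n_arc_samples arc (row) samples per slice; fixed across slices so
#'   boundary surfaces share a row grid.
#' @param inner_margin_vox,outer_depth_vox unwrapped-frame extents.
#' @param opening_length_vox vertical structuring-element length.
#' @param island_min_px minimum component size kept after opening.
#' @param gmm_components mixture components for the edge model.
#' @param base_weight,edge_bonus,mask_penalty,tolerance weight-image
#'   parameters ([build_weight_image()]).
#' @param lambda,d_max geodesic deviation penalty and step bound; `NULL`
#'   lambda defaults to `0.5 * edge_bonus / d_max`.
#' @param smooth_sd_row,smooth_sd_slice boundary-surface smoothing SDs.
#' @param refine_subvoxel logical: refine boundary/outer-edge positions to
#'   the local half-contrast crossing before smoothing.
#' @param refine_halfwidth_vox half-width of the refinement window.
#' @return A `segment_config` list.
#' @export
segment_config <- function(bilateral_window_vox = 7L,
                           bilateral_sigma_spatial = 1.5,
                           bilateral_sigma_range = NULL,
                           spline_smoothing = 1,
                           spline_basis_dim = 16L,
                           n_arc_samples = 360L,
                           inner_margin_vox = 5L,
                           outer_depth_vox = 80L,
                           opening_length_vox = 9L,
                           island_min_px = 60L,
                           gmm_components = 2L,
                           base_weight = 1, edge_bonus = 2,
                           mask_penalty = 0.5, tolerance = NULL,
                           lambda = NULL, d_max = 2L,
                           smooth_sd_row = 3, smooth_sd_slice = 2,
                           refine_subvoxel = TRUE,
                           refine_halfwidth_vox = 4L) {
  cfg <- as.list(environment())
  if (!is.null(cfg$lambda) && cfg$lambda < 0)
    stop("lambda must be >= 0")
  if (cfg$d_max < 1L) stop("d_max must be >= 1")
  if (cfg$outer_depth_vox <= cfg$inner_margin_vox)
    stop("outer_depth_vox must exceed inner_margin_vox")
  structure(cfg, class = "segment_config")
}

#' Segment an arterial-wall tomogram into layers
#'
#' Applies the full per-slice protocol: axial bilateral filtering, lumen
#' edge detection and periodic spline fit, unwrapping, grey-level
#' thresholding (texture threshold by Otsu; a darker wall threshold from a
#' second Otsu pass on the sub-threshold population separates paraffin from
#' adventitial ground), vertical opening and island removal, the per-row
#' edge profile and its Gaussian-mixture model, geodesic extraction of the
#' media-adventitia boundary, optional sub-voxel refinement, 3D smoothing of
#' the boundary and outer-wall surfaces, and re-wrapping into a label
#' volume. Slices whose lumen cannot be detected are flagged for manual
#' review and left unlabelled.
#'
#' @param vol a [tomogram()].
#' @param config a [segment_config()].
#' @return A `layer_segmentation`: list with `labels` (integer array; 0
#'   background, 1 lumen, 2 media, 3 adventitia), `boundary` and
#'   `outer_edge` (matrices of smoothed sub-voxel columns, rows x slices),
#'   `contours` (tibble: slice, row, col, x, y of the boundary),
#'   `transforms` (per-slice `unwrap_transform`s), `diagnostics` (per-slice
#'   tibble) and `config`.
#' @export
segment_volume <- function(vol, config = segment_config()) {
  vol <- as_tomogram(vol)
  filt <- bilateral_filter_axial(vol,
                                 sigma_spatial_vox = config$bilateral_sigma_spatial,
                                 sigma_range_grey = config$bilateral_sigma_range,
                                 window_vox = config$bilateral_window_vox)
  nz <- n_slices(filt)
  nrows <- config$n_arc_samples
  B <- matrix(NA_real_, nrows, nz)
  O <- matrix(NA_real_, nrows, nz)
  transforms <- vector("list", nz)
  lumen_edges <- vector("list", nz)
  masks_tex <- vector("list", nz)
  diag_rows <- vector("list", nz)

  for (z in seq_len(nz)) {
    slice <- filt$values[, , z]
    rec <- list(slice = z, status = "ok", threshold_tex = NA_real_,
                threshold_wall = NA_real_, xbar_e = NA_real_,
                path_cost = NA_real_, n_flagged_rows = 0L)
    res <- tryCatch({
      th0 <- otsu_threshold(slice)
      edge <- detect_lumen_edge(slice, th0)
      spline <- fit_lumen_spline(edge, config$spline_smoothing,
                                 config$spline_basis_dim)
      uw <- unwrap_slice(slice, spline,
                         n_arc_samples = nrows,
                         inner_margin_vox = config$inner_margin_vox,
                         outer_depth_vox = config$outer_depth_vox)
      img <- uw$image
      mask_tex <- threshold_wall(img, "otsu")
      th_tex <- attr(mask_tex, "threshold")
      sub <- img[img < th_tex]
      th_wall <- tryCatch(otsu_threshold(sub), error = function(e) th_tex)
      mask_wall <- img >= th_wall
      opened <- remove_islands(open_vertical(mask_tex, config$opening_length_vox),
                               config$island_min_px)
      prof <- edge_profile(opened)
      model <- fit_edge_model(prof, config$gmm_components,
                              tolerance = config$tolerance)
      Wimg <- build_weight_image(mask_tex, model, prof,
                                 base_weight = config$base_weight,
                                 edge_bonus = config$edge_bonus,
                                 mask_penalty = config$mask_penalty,
                                 tolerance = config$tolerance)
      path <- trace_geodesic_boundary(Wimg, lambda = config$lambda,
                                      d_max = config$d_max)
      b <- as.numeric(path$col)
      wall_clean <- remove_islands(mask_wall, config$island_min_px)
      oprof <- edge_profile(wall_clean)
      o <- as.numeric(oprof$xe)
      o[is.na(o)] <- stats::median(o, na.rm = TRUE)
      if (config$refine_subvoxel) {
        b <- fill_periodic_na(refine_crossing(img, b,
                                              config$refine_halfwidth_vox))
        # outer wall/paraffin interface: a fixed half-way level between the
        # global paraffin and adventitial-ground class medians is more
        # robust than local plateaus (fibres contaminate the inside window)
        paraffin_med <- stats::median(img[img < th_wall])
        ground_med <- stats::median(img[img >= th_wall & img < th_tex])
        o <- fill_periodic_na(refine_crossing(img, o,
                                              config$refine_halfwidth_vox,
                                              level = (paraffin_med + ground_med) / 2))
      }
      rec$threshold_tex <- th_tex
      rec$threshold_wall <- th_wall
      rec$xbar_e <- model$dominant_mean
      rec$path_cost <- attr(path, "cost")
      rec$n_flagged_rows <- length(uw$transform$flagged_rows)
      list(b = b, o = o, tr = uw$transform, edge = edge, mask = mask_tex)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      rec$status <- paste0("flagged: ", conditionMessage(res))
    } else {
      B[, z] <- res$b
      O[, z] <- res$o
      transforms[[z]] <- res$tr
      lumen_edges[[z]] <- res$edge
      masks_tex[[z]] <- res$mask
    }
    diag_rows[[z]] <- tibble::as_tibble(rec)
  }
  diagnostics <- dplyr::bind_rows(diag_rows)
  ok <- !is.na(B[1, ])
  if (!any(ok))
    stop("segmentation failed on every slice; first error: ",
         diagnostics$status[1])

  Bs <- B; Os <- O
  Bs[, ok] <- smooth_boundary_surface(B[, ok, drop = FALSE],
                                      config$smooth_sd_row,
                                      config$smooth_sd_slice)
  Os[, ok] <- smooth_boundary_surface(O[, ok, drop = FALSE],
                                      config$smooth_sd_row,
                                      config$smooth_sd_slice)

  d <- dim(vol$values)
  labels <- array(LABEL_BACKGROUND, d)
  contour_rows <- vector("list", nz)
  for (z in which(ok)) {
    tr <- transforms[[z]]
    bxy <- rewrap_points(cbind(seq_len(nrows), pmin(pmax(Bs[, z], 1), tr$n_col)), tr)
    oxy <- rewrap_points(cbind(seq_len(nrows), pmin(pmax(Os[, z], 1), tr$n_col)), tr)
    labels[, , z] <- label_slice(d[1], d[2], lumen_edges[[z]], bxy, oxy,
                                 tr$spline$centroid)
    contour_rows[[z]] <- tibble::tibble(slice = z, row = seq_len(nrows),
                                        col = Bs[, z], x = bxy$x, y = bxy$y)
  }
  structure(list(labels = labels, boundary = Bs, outer_edge = Os,
                 contours = dplyr::bind_rows(contour_rows),
                 transforms = transforms,
                 lumen_contours = lumen_edges,
                 diagnostics = diagnostics,
                 voxel_size_um = vol$voxel_size_um,
                 config = config),
            class = "layer_segmentation")
}

#' @export
print.layer_segmentation <- function(x, ...) {
  nz <- dim(x$labels)[3]
  nok <- sum(!startsWith(x$diagnostics$status, "flagged"))
  cat(sprintf("<layer_segmentation> %d/%d slices segmented, %d arc rows, voxel %.3g um\n",
              nok, nz, nrow(x$boundary), x$voxel_size_um))
  invisible(x)
}

# Sub-voxel interface refinement: around each integer boundary column, take
# robust inside/outside plateau levels and locate the half-contrast crossing
# of the (decreasing) radial profile by linear interpolation. Falls back to
# the input position when the local profile does not cross.
refine_crossing <- function(img, cols, halfwidth = 4L, level = NULL) {
  nr <- nrow(img); nc <- ncol(img)
  out <- cols
  for (r in seq_len(nr)) {
    b <- round(cols[r])
    if (is.na(b)) next
    lo <- b - halfwidth; hi <- b + halfwidth
    if (lo < 1L || hi > nc) next
    seg <- img[r, lo:hi]
    if (is.null(level)) {
      inside <- stats::median(seg[1:(halfwidth - 1L)])
      outside <- stats::median(seg[(halfwidth + 3L):(2L * halfwidth + 1L)])
      if (!(inside > outside)) next
      lv <- (inside + outside) / 2
    } else lv <- level
    above <- seg >= lv
    cross <- which(above[-length(seg)] & !above[-1])
    if (!length(cross)) { out[r] <- NA_real_; next }
    j <- cross[1L]   # first crossing walking outward from the inside plateau
    frac <- (seg[j] - lv) / (seg[j] - seg[j + 1L])
    out[r] <- lo + (j - 1L) + frac
  }
  out
}

# Fill NA entries of a periodic (row-wrapped) profile by linear
# interpolation from the surviving entries.
fill_periodic_na <- function(x) {
  n <- length(x)
  if (!anyNA(x)) return(x)
  good <- which(!is.na(x))
  if (!length(good)) return(x)
  idx <- c(good, good + n)
  val <- c(x[good], x[good])
  out <- approx(idx, val, xout = seq_len(n) + n, rule = 2)$y
  out
}

# Label one trans-axial slice from its three closed interfaces, all
# star-shaped about the lumen centroid: lumen edge points (sub-voxel),
# rewrapped boundary points and rewrapped outer-edge points.
label_slice <- function(nr, nc, lumen_pts, boundary_xy, outer_xy, centre) {
  cx <- centre[1]; cy <- centre[2]
  pr <- matrix(seq_len(nr), nr, nc)
  pc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  r_pix <- sqrt((pc - cx)^2 + (pr - cy)^2)
  th_pix <- atan2(pr - cy, pc - cx)
  rad_of <- function(x, y) {
    th <- atan2(y - cy, x - cx)
    rad <- sqrt((x - cx)^2 + (y - cy)^2)
    interp_periodic(th, rad, as.vector(th_pix))
  }
  r_l <- rad_of(lumen_pts[, 1], lumen_pts[, 2])
  r_b <- rad_of(boundary_xy$x, boundary_xy$y)
  r_o <- rad_of(outer_xy$x, outer_xy$y)
  lab <- matrix(LABEL_BACKGROUND, nr, nc)
  v <- as.vector(r_pix)
  lab[v < r_o] <- LABEL_ADVENTITIA
  lab[v < r_b] <- LABEL_MEDIA
  lab[v < r_l] <- LABEL_LUMEN
  lab
}
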