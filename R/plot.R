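# ggplot2 views of the main result types.

#' Plot an unwrapped luminal surface map
#'
#' Height-map view of the luminal radius residuals over (arc position,
#' slice); axis-oriented ripples appear as vertical bands.
#'
#' @param map a [luminal_surface_map()] result.
#' @param residual plot residuals (default) or absolute radius.
#' @return A ggplot.
#' @export
plot_surface_map <- function(map, residual = TRUE) {
  m <- if (residual) map$residual_um else map$radius_um
  df <- tidyr::expand_grid(slice = seq_len(ncol(m)),
                           arc = seq_len(nrow(m)))
  df$value <- as.vector(m[cbind(df$arc, df$slice)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$arc, y = .data$slice,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(name = if (residual) "residual (um)"
                                  else "radius (um)") +
    ggplot2::labs(x = "arc sample (circumference)", y = "slice (axial)",
                  title = "Unwrapped luminal surface") +
    ggplot2::theme_minimal()
}

#' Boundary overlay on a trans-axial slice
#'
#' @param vol a [tomogram()].
#' @param seg a `layer_segmentation`.
#' @param slice slice index.
#' @return A ggplot showing the slice with the media-adventitia boundary.
#' @export
plot_boundary_overlay <- function(vol, seg, slice = 1L) {
  vol <- as_tomogram(vol)
  m <- vol$values[, , slice]
  df <- tidyr::expand_grid(y = seq_len(nrow(m)), x = seq_len(ncol(m)))
  df$value <- as.vector(m[cbind(df$y, df$x)])
  ct <- dplyr::filter(seg$contours, .data$slice == !!slice)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::geom_path(data = ct, colour = "orange", linewidth = 0.4) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("Media-adventitia boundary, slice %d", slice),
                  x = NULL, y = NULL) +
    ggplot2::theme_void()
}

#' Frequency-distribution histograms of per-slice thickness
#'
#' Layer-thickness histograms, optionally split by group.
#'
#' @param table a [morphometry_table()] tibble (a `group` column is used
#'   for facetting when present).
#' @param binwidth_um histogram bin width in micrometres.
#' @return A ggplot.
#' @export
plot_thickness_histograms <- function(table, binwidth_um = 0.25) {
  long <- tidyr::pivot_longer(table,
                              c("medial_thickness_um",
                                "adventitial_thickness_um"),
                              names_to = "layer", values_to = "thickness_um")
  long$layer <- sub("_thickness_um", "", long$layer)
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$thickness_um))
  if ("group" %in% names(long))
    p <- p + ggplot2::aes(fill = .data$group)
  p + ggplot2::geom_histogram(binwidth = binwidth_um, position = "identity",
                              alpha = 0.6) +
    ggplot2::facet_wrap(~layer, scales = "free") +
    ggplot2::labs(x = "mean layer thickness per slice (um)", y = "slices") +
    ggplot2::theme_minimal()
}
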