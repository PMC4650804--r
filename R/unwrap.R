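# Unwrapping: resample the wall along lines perpendicular to the lumen
# spline so the annular wall becomes a rectangular strip in which the
# elastic lamellae run as (near-)vertical lines down the rows.

#' Unwrap a trans-axial slice around its lumen spline
#'
#' Row `r` of the unwrapped image corresponds to arc position
#' `(r - 1) * perimeter / n_arc_samples` along the spline; column `c` to the
#' signed radial offset `(c - 1 - inner_margin_vox)` voxels along the
#' outward normal (so column `inner_margin_vox + 1` lies exactly on the
#' spline). Intensities are sampled bilinearly. Rows whose outward normals
#' cross before `outer_depth_vox` (strong local concavity) are reported in
#' the `flagged_rows` attribute of the transform.
#'
#' @param slice2d numeric matrix `[row, col]`.
#' @param spline a [fit_lumen_spline()] result.
#' @param n_arc_samples number of arc (row) samples; default
#'   `ceiling(perimeter)`, i.e. about 1 voxel of row spacing.
#' @param inner_margin_vox columns kept inside the lumen edge.
#' @param outer_depth_vox columns sampled outward from the lumen edge; must
#'   cover the wall plus a paraffin margin.
#' @return list with `image` (matrix, rows = arc, cols = radial offset) and
#'   `transform` (an `unwrap_transform`).
#' @export
unwrap_slice <- function(slice2d, spline, n_arc_samples = NULL,
                         inner_margin_vox = 5L, outer_depth_vox = 80L) {
  if (!inherits(spline, "lumen_spline")) stop("`spline` must be a lumen_spline")
  if (is.null(n_arc_samples)) n_arc_samples <- ceiling(spline$perimeter)
  n_arc_samples <- as.integer(n_arc_samples)
  if (n_arc_samples < 4L) stop("need at least 4 arc samples")
  inner_margin_vox <- as.integer(inner_margin_vox)
  outer_depth_vox <- as.integer(outer_depth_vox)
  s <- (seq_len(n_arc_samples) - 1) * spline$perimeter / n_arc_samples
  anchors <- spline_at_arc(spline, s)
  offsets <- seq_len(inner_margin_vox + outer_depth_vox) - 1L - inner_margin_vox
  X <- outer(anchors$x, rep(1, length(offsets))) +
    outer(anchors$nx, offsets)
  Y <- outer(anchors$y, rep(1, length(offsets))) +
    outer(anchors$ny, offsets)
  img <- matrix(bilinear_sample(slice2d, as.vector(X), as.vector(Y)),
                nrow = n_arc_samples)
  flagged <- which(anchors$kappa < -1 / outer_depth_vox)
  tr <- structure(list(anchors = anchors, spline = spline,
                       n_arc = n_arc_samples,
                       inner_margin = inner_margin_vox,
                       outer_depth = outer_depth_vox,
                       n_col = length(offsets),
                       perimeter = spline$perimeter,
                       flagged_rows = flagged),
                  class = "unwrap_transform")
  structure(list(image = img, transform = tr), class = "unwrapped_image")
}

#' Map unwrapped-frame points back onto the trans-axial slice
#'
#' Closed-form inverse of the unwrapping: a point at (row, col) maps to
#' `spline(arc(row)) + (col - 1 - inner_margin) * outward_normal`.
#' Fractional rows and columns are allowed (rows address arc positions
#' continuously).
#'
#' @param points_unwrapped two-column matrix or data frame `(row, col)`.
#' @param transform an `unwrap_transform` from [unwrap_slice()].
#' @return Tibble with trans-axial `x`, `y` coordinates.
#' @export
rewrap_points <- function(points_unwrapped, transform) {
  if (!inherits(transform, "unwrap_transform"))
    stop("`transform` must be an unwrap_transform")
  p <- as.matrix(points_unwrapped)
  row <- p[, 1]; col <- p[, 2]
  bad <- which(row < 1 | row > transform$n_arc + 1 - 1e-9 |
                 col < 1 | col > transform$n_col)
  if (length(bad))
    stop("points outside the unwrapped frame at indices: ",
         paste(head(bad, 10), collapse = ", "))
  s <- (row - 1) * transform$perimeter / transform$n_arc
  a <- spline_at_arc(transform$spline, s)
  off <- col - 1 - transform$inner_margin
  tibble::tibble(x = a$x + off * a$nx, y = a$y + off * a$ny)
}

#' Project trans-axial points into the unwrapped frame
#'
#' Forward companion of [rewrap_points()]: each point is assigned the arc
#' row of its nearest spline anchor and the signed normal offset from it.
#' Accurate to about half the arc sample spacing inside the wall band.
#'
#' @param points_xy two-column matrix `(x, y)`.
#' @param transform an `unwrap_transform`.
#' @return Tibble with fractional `row` and `col` unwrapped coordinates.
#' @export
unwrap_points <- function(points_xy, transform) {
  p <- as.matrix(points_xy)
  a <- transform$anchors
  n <- nrow(p)
  row <- numeric(n); col <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- (a$x - p[i, 1])^2 + (a$y - p[i, 2])^2
    r <- which.min(d2)
    dxp <- p[i, 1] - a$x[r]; dyp <- p[i, 2] - a$y[r]
    off <- dxp * a$nx[r] + dyp * a$ny[r]
    along <- dxp * a$tx[r] + dyp * a$ty[r]
    row[i] <- r + along / (transform$perimeter / transform$n_arc)
    col[i] <- off + 1 + transform$inner_margin
  }
  tibble::tibble(row = row, col = col)
}

#' @export
print.unwrap_transform <- function(x, ...) {
  cat(sprintf("<unwrap_transform> %d arc rows, %d radial cols (margin %d), perimeter %.1f vox, %d flagged rows\n",
              x$n_arc, x$n_col, x$inner_margin, x$perimeter,
              length(x$flagged_rows)))
  invisible(x)
}
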