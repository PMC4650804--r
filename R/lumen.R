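# Lumen edge detection and periodic spline fitting: the anchor of the
# unwrapping transform.

#' Detect the lumen edge on a trans-axial slice
#'
#' Traces the inner wall boundary as a sub-voxel iso-contour (marching
#' squares, via [grDevices::contourLines()]) at the wall threshold, keeping
#' the smallest closed contour that encloses `centre_hint`. When `refine` is
#' `TRUE` the contour level is re-estimated as the half-way grey level
#' between the lumen interior and the wall band just outside the first-pass
#' contour and the contour is retraced, which removes the systematic radial
#' bias an arbitrary threshold level introduces on blurred interfaces.
#'
#' @param slice2d numeric matrix (one trans-axial slice, `[row, col]`).
#' @param wall_threshold grey level separating lumen interior from wall.
#' @param centre_hint length-2 `(x = col, y = row)` point inside the lumen;
#'   default is the centroid of below-threshold pixels.
#' @param refine logical; re-estimate the contour level (default `TRUE`).
#' @return A two-column matrix `(x, y)` of ordered, counter-clockwise
#'   (positive signed area) sub-voxel edge points, with attributes `level`
#'   (contour grey level) and `centre` (the hint used).
#' @export
detect_lumen_edge <- function(slice2d, wall_threshold, centre_hint = NULL,
                              refine = TRUE) {
  if (!is.matrix(slice2d)) stop("slice2d must be a matrix")
  if (!all(is.finite(slice2d))) stop("non-finite pixels in slice")
  if (is.null(centre_hint)) {
    idx <- which(slice2d < wall_threshold, arr.ind = TRUE)
    if (!nrow(idx)) stop("lumen not found: no pixels below threshold")
    centre_hint <- c(mean(idx[, 2]), mean(idx[, 1]))
  }
  cy <- centre_hint[2]; cx <- centre_hint[1]
  hv <- slice2d[pmin(pmax(round(cy), 1), nrow(slice2d)),
                pmin(pmax(round(cx), 1), ncol(slice2d))]
  if (hv >= wall_threshold)
    stop("lumen not found: centre hint is not inside a below-threshold region")
  pts <- trace_enclosing_contour(slice2d, wall_threshold, cx, cy)
  if (refine) {
    rad <- sqrt((pts[, 1] - cx)^2 + (pts[, 2] - cy)^2)
    th <- atan2(pts[, 2] - cy, pts[, 1] - cx)
    pr <- matrix(seq_len(nrow(slice2d)), nrow(slice2d), ncol(slice2d))
    pc <- matrix(seq_len(ncol(slice2d)), nrow(slice2d), ncol(slice2d),
                 byrow = TRUE)
    r_pix <- sqrt((pc - cx)^2 + (pr - cy)^2)
    th_pix <- atan2(pr - cy, pc - cx)
    r_edge <- interp_periodic(th, rad, as.vector(th_pix))
    inside <- as.vector(r_pix) < 0.6 * r_edge
    band <- as.vector(r_pix) > r_edge + 1.5 & as.vector(r_pix) < r_edge + 4
    if (any(inside) && any(band)) {
      # lower-quartile band level: the tissue immediately outside the lumen
      # edge is the darker interlamellar ground, but the band can also catch
      # the first bright lamella, which must not lift the contour level
      level <- (mean(slice2d[inside]) +
                  unname(quantile(slice2d[band], 0.25))) / 2
      pts2 <- tryCatch(trace_enclosing_contour(slice2d, level, cx, cy),
                       error = function(e) NULL)
      if (!is.null(pts2)) {
        attr(pts2, "level") <- level
        attr(pts2, "centre") <- c(cx, cy)
        return(pts2)
      }
    }
  }
  attr(pts, "level") <- wall_threshold
  attr(pts, "centre") <- c(cx, cy)
  pts
}

# Smallest closed iso-contour at `level` enclosing (cx, cy); CCW order.
trace_enclosing_contour <- function(slice2d, level, cx, cy) {
  cl <- grDevices::contourLines(x = seq_len(nrow(slice2d)),
                                y = seq_len(ncol(slice2d)),
                                z = slice2d, levels = level)
  if (!length(cl)) stop("lumen not found: no contour at threshold level")
  best <- NULL; best_area <- Inf
  for (cc in cl) {
    x <- cc$y; y <- cc$x   # convert to (x = col, y = row)
    n <- length(x)
    if (n < 8) next
    closed <- sqrt((x[1] - x[n])^2 + (y[1] - y[n])^2) < 1.5
    if (!closed) next
    if (x[1] == x[n] && y[1] == y[n]) { x <- x[-n]; y <- y[-n]; n <- n - 1 }
    if (!point_in_polygon(cx, cy, x, y)) next
    a <- abs(polygon_area(x, y))
    if (a < best_area) { best_area <- a; best <- cbind(x = x, y = y) }
  }
  if (is.null(best))
    stop("lumen not found: no closed contour encloses the centre hint")
  if (polygon_area(best[, 1], best[, 2]) < 0) best <- best[rev(seq_len(nrow(best))), ]
  best
}

polygon_area <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1)
  0.5 * sum(x * y[j] - x[j] * y)
}

point_in_polygon <- function(px, py, x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  cross <- ((y > py) != (y[j] > py)) &
    (px < (x[j] - x) * (py - y) / (y[j] - y) + x)
  sum(cross) %% 2 == 1
}

#' Fit a closed periodic smoothing spline to lumen edge points
#'
#' Parameterises the ordered edge points by normalised cumulative chord
#' length and fits periodic splines to x and y. With
#' `smoothing_parameter = 0` the points are interpolated exactly (periodic
#' cubic spline); positive values fit cyclic penalised regression splines
#' (via [mgcv::gam()] with a `"cc"` basis, `sp = smoothing_parameter`). The
#' fitted curve is resampled densely and stored with an arc-length table so
#' it can be evaluated at any arc position in closed form.
#'
#' @param points two-column `(x, y)` matrix of ordered closed edge points.
#' @param smoothing_parameter non-negative smoothing parameter.
#' @param basis_dim cyclic-basis dimension for the smoothing fit; it caps
#'   the angular frequency the spline can follow, so the unwrapping anchor
#'   tracks the overall lumen shape but not high-frequency surface ripples
#'   (whose curvature would make outward normals cross inside the wall).
#' @return A `lumen_spline` object: evaluation functions, perimeter and the
#'   arc-length parameterisation.
#' @export
fit_lumen_spline <- function(points, smoothing_parameter = 0,
                             basis_dim = 16L) {
  points <- as.matrix(points)
  if (nrow(points) < 8L) stop("need at least 8 edge points")
  if (smoothing_parameter < 0) stop("smoothing_parameter must be >= 0")
  x <- points[, 1]; y <- points[, 2]
  if (polygon_area(x, y) < 0) { x <- rev(x); y <- rev(y) }
  seg <- sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2)
  keep <- c(TRUE, seg[-length(seg)] > 1e-9)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 8L) stop("need at least 8 distinct edge points")
  seg <- sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2)
  tt <- c(0, cumsum(seg)) / sum(seg)   # length n + 1, closes at 1

  if (smoothing_parameter == 0) {
    fx <- splinefun(tt, c(x, x[1]), method = "periodic")
    fy <- splinefun(tt, c(y, y[1]), method = "periodic")
  } else {
    k <- max(8L, min(n - 1L, as.integer(basis_dim)))
    if (n > 256L) {          # the penalised fit needs no more support
      sub <- unique(round(seq(1L, n, length.out = 256L)))
      dat <- data.frame(t = tt[sub], x = x[sub], y = y[sub])
    } else
      dat <- data.frame(t = tt[-(n + 1L)], x = x, y = y)
    gx <- mgcv::gam(x ~ s(t, bs = "cc", k = k), data = dat,
                    knots = list(t = seq(0, 1, length.out = k)),
                    sp = smoothing_parameter)
    gy <- mgcv::gam(y ~ s(t, bs = "cc", k = k), data = dat,
                    knots = list(t = seq(0, 1, length.out = k)),
                    sp = smoothing_parameter)
    td <- seq(0, 1, length.out = 1025L)
    px <- stats::predict(gx, newdata = data.frame(t = td))
    py <- stats::predict(gy, newdata = data.frame(t = td))
    px[1025L] <- px[1L]; py[1025L] <- py[1L]
    fx <- splinefun(td, px, method = "periodic")
    fy <- splinefun(td, py, method = "periodic")
  }

  td <- seq(0, 1, length.out = 4097L)
  dx <- fx(td); dy <- fy(td)
  s <- c(0, cumsum(sqrt(diff(dx)^2 + diff(dy)^2)))
  perimeter <- s[length(s)]
  t_of_s <- stats::approxfun(s, td, rule = 2)

  sp <- structure(list(fx = fx, fy = fy, t_of_s = t_of_s,
                       perimeter = perimeter,
                       centroid = c(mean(dx[-length(dx)]), mean(dy[-length(dy)])),
                       n_points = n,
                       smoothing = smoothing_parameter),
                  class = "lumen_spline")
  if (spline_self_intersects(sp))
    stop("fitted lumen spline is self-intersecting")
  sp
}

#' Evaluate a lumen spline at arc positions
#'
#' @param spline a `lumen_spline`.
#' @param s arc positions (voxels along the curve, wrapped modulo the
#'   perimeter).
#' @return Tibble with point coordinates `x`, `y`, unit tangent `tx`, `ty`,
#'   outward unit normal `nx`, `ny` and signed curvature `kappa`
#'   (positive = locally convex).
#' @export
spline_at_arc <- function(spline, s) {
  t <- spline$t_of_s(s %% spline$perimeter)
  x <- spline$fx(t); y <- spline$fy(t)
  d1x <- spline$fx(t, deriv = 1); d1y <- spline$fy(t, deriv = 1)
  d2x <- spline$fx(t, deriv = 2); d2y <- spline$fy(t, deriv = 2)
  sp <- sqrt(d1x^2 + d1y^2)
  sp[sp == 0] <- 1e-12
  tx <- d1x / sp; ty <- d1y / sp
  kappa <- (d1x * d2y - d1y * d2x) / sp^3
  tibble::tibble(s = s, x = x, y = y, tx = tx, ty = ty,
                 nx = ty, ny = -tx, kappa = kappa)
}

spline_self_intersects <- function(spline, n_check = 96L) {
  s <- seq(0, spline$perimeter, length.out = n_check + 1L)
  p <- spline_at_arc(spline, s[-(n_check + 1L)])
  x <- p$x; y <- p$y
  n <- length(x)
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  pair <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- pair[, 1]; j <- pair[, 2]
  keep <- (j - i) >= 2L & !(i == 1L & j == n)   # skip adjacent segments
  i <- i[keep]; j <- j[keep]
  any(segments_intersect(x[i], y[i], x2[i], y2[i],
                         x[j], y[j], x2[j], y2[j]))
}

segments_intersect <- function(ax, ay, bx, by, cx, cy, dx, dy) {
  d1 <- (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  d2 <- (bx - ax) * (dy - ay) - (by - ay) * (dx - ax)
  d3 <- (dx - cx) * (ay - cy) - (dy - cy) * (ax - cx)
  d4 <- (dx - cx) * (by - cy) - (dy - cy) * (bx - cx)
  (d1 * d2 < 0) & (d3 * d4 < 0)
}
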