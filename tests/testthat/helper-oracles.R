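# Independent brute-force oracles used to verify the package's operations.
# These deliberately use naive algorithms, not the implementation's path.

# Exhaustive within-class-variance minimiser (Otsu oracle).
naive_otsu <- function(values) {
  v <- sort(unique(as.vector(values)))
  best <- Inf; thr <- NA
  for (i in seq_len(length(v) - 1L)) {
    t <- (v[i] + v[i + 1L]) / 2
    a <- values[values < t]; b <- values[values >= t]
    wcv <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    if (wcv < best) { best <- wcv; thr <- t }
  }
  thr
}

# Pixel-by-pixel binary erosion / dilation with a vertical line element.
naive_erode_v <- function(mask, len) {
  h <- (len - 1L) %/% 2L
  nr <- nrow(mask); out <- mask
  for (r in seq_len(nr)) for (c in seq_len(ncol(mask))) {
    win <- max(1L, r - h):min(nr, r + h)
    full <- (r - h) >= 1L && (r + h) <= nr
    out[r, c] <- if (full) all(mask[win, c]) else FALSE
  }
  out
}

naive_dilate_v <- function(mask, len) {
  h <- (len - 1L) %/% 2L
  nr <- nrow(mask); out <- mask
  for (r in seq_len(nr)) for (c in seq_len(ncol(mask))) {
    win <- max(1L, r - h):min(nr, r + h)
    out[r, c] <- any(mask[win, c])
  }
  out
}

# Recursive flood fill (8-connected) component filter.
flood_fill_filter <- function(mask, min_size) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  out <- matrix(FALSE, nr, nc)
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (!mask[r0, c0] || seen[r0, c0]) next
    comp <- matrix(c(r0, c0), ncol = 2)
    seen[r0, c0] <- TRUE
    queue <- list(c(r0, c0))
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dr in -1:1) for (dc in -1:1) {
        rr <- p[1] + dr; cc <- p[2] + dc
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
        if (mask[rr, cc] && !seen[rr, cc]) {
          seen[rr, cc] <- TRUE
          comp <- rbind(comp, c(rr, cc))
          queue <- c(queue, list(c(rr, cc)))
        }
      }
    }
    if (nrow(comp) >= min_size) out[comp] <- TRUE
  }
  out
}

# Exhaustive enumeration of every feasible row-monotone path (|step| <= dmax)
# including the periodic-closure penalty; returns the global minimum cost.
brute_force_geodesic_cost <- function(W, lambda, dmax = 1L) {
  cost <- max(W) - W
  R <- nrow(cost); C <- ncol(cost)
  steps <- as.matrix(expand.grid(rep(list(seq(-dmax, dmax)), R - 1L)))
  np <- nrow(steps)
  cum <- matrix(0L, np, R)
  for (j in 2:R) cum[, j] <- cum[, j - 1L] + steps[, j - 1L]
  minc <- apply(cum, 1, min); maxc <- apply(cum, 1, max)
  pen <- lambda * rowSums(abs(steps)) + lambda * abs(cum[, R])
  best <- Inf
  for (s in seq_len(C)) {
    ok <- (s + minc) >= 1L & (s + maxc) <= C
    if (!any(ok)) next
    nc <- rep(0, np)
    for (r in seq_len(R))    # clamped lookups; infeasible rows filtered below
      nc <- nc + cost[r, pmin(pmax(cum[, r] + s, 1L), C)]
    tot <- nc[ok] + pen[ok]
    best <- min(best, min(tot))
  }
  best
}

# Dice overlap of two logical arrays.
dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# Small, fast phantom spec for unit tests (callers may override any field).
small_spec <- function(...) {
  defaults <- list(image_shape = c(6L, 160L, 160L),
                   lumen_radius_vox = 30,
                   ripple_amplitude_vox = 1.5,
                   ripple_wavelength_vox = 20,
                   n_lamellae = 3L,
                   lamella_thickness_vox = 2.5,
                   interlamellar_gap_vox = 4,
                   waviness_amplitude_vox = 1,
                   adventitia_thickness_vox = 12,
                   pore_count = 0L,
                   noise_sd = 0)
  do.call(phantom_spec, utils::modifyList(defaults, list(...)))
}

# Median absolute radial error of the extracted boundary against ground
# truth, per slice, evaluated at the contour points' angles.
boundary_radial_errors <- function(seg, gt) {
  nz <- dim(gt$labels)[3]
  vapply(seq_len(nz), function(z) {
    ct <- seg$contours[seg$contours$slice == z, ]
    if (!nrow(ct)) return(NA_real_)
    cen <- gt$centres[z, ]
    rpred <- sqrt((ct$x - cen["col"])^2 + (ct$y - cen["row"])^2)
    thp <- atan2(ct$y - cen["row"], ct$x - cen["col"])
    rtrue <- approx(c(gt$boundary_theta - 2 * pi, gt$boundary_theta,
                      gt$boundary_theta + 2 * pi),
                    rep(gt$boundary_radius[, z], 3), xout = thp)$y
    median(abs(rpred - rtrue))
  }, numeric(1))
}
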