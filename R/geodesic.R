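# Weighted-image construction and exact minimal-path boundary extraction.

#' Build the geodesic weight image
#'
#' Weights start at `base_weight` everywhere. Pixels inside the initial
#' thresholded wall mask are lowered by `mask_penalty` (the path should run
#' just outside the wall, not through it); then the candidate boundary pixel
#' of each row -- column `xe + 1` -- receives `edge_bonus` extra weight when
#' it lies within `tolerance` of the mean edge position. The penalty is
#' applied before the bonus, so a pixel that is both in-mask and qualifying
#' nets `base - penalty + bonus`. Weights are clipped at zero.
#'
#' @param mask logical matrix: the initial thresholded image (before
#'   opening/island removal).
#' @param model an [fit_edge_model()] result (supplies the mean edge
#'   position and default tolerance).
#' @param profile an [edge_profile()] tibble (supplies per-row `xe`),
#'   normally computed from the texture-filtered mask.
#' @param base_weight,edge_bonus,mask_penalty weight parameters;
#'   `edge_bonus > 0`, `0 < mask_penalty <= base_weight`.
#' @param tolerance closeness tolerance; default from `model`.
#' @return A `weight_image`: list with `weights` matrix and `params`.
#' @export
build_weight_image <- function(mask, model, profile,
                               base_weight = 1, edge_bonus = 2,
                               mask_penalty = 0.5, tolerance = NULL) {
  if (base_weight <= 0) stop("base_weight must be > 0")
  if (edge_bonus <= 0) stop("edge_bonus must be > 0")
  if (mask_penalty <= 0 || mask_penalty > base_weight)
    stop("mask_penalty must be in (0, base_weight]")
  tolerance <- tolerance %||% model$tolerance
  W <- matrix(base_weight, nrow(mask), ncol(mask))
  W[mask] <- base_weight - mask_penalty
  cand <- profile$xe + 1L
  ok <- !profile$missing & !is.na(cand) & cand >= 1L & cand <= ncol(mask) &
    abs(cand - model$dominant_mean) <= tolerance
  if (any(ok))
    W[cbind(profile$row[ok], cand[ok])] <-
      W[cbind(profile$row[ok], cand[ok])] + edge_bonus
  W[W < 0] <- 0
  structure(list(weights = W,
                 params = list(base_weight = base_weight,
                               edge_bonus = edge_bonus,
                               mask_penalty = mask_penalty,
                               tolerance = tolerance,
                               mean_edge = model$dominant_mean)),
            class = "weight_image")
}

#' Extract the media-adventitia boundary as an exact geodesic path
#'
#' Finds the column sequence `c[1..n_rows]` (one column per row) minimising
#' \deqn{\sum_r (W_{max} - W(r, c_r)) + \lambda \sum_r |c_r - c_{r-1}| +
#'   \lambda |c_{n} - c_1|}
#' subject to `|c_r - c_{r-1}| <= d_max` between adjacent rows (the closure
#' term across the row wrap is penalised but unconstrained). Subtracting the
#' weights from their maximum turns attraction to large weights into a
#' shortest-path problem, solved exactly by dynamic programming on the
#' row-layered graph (conditioning on the start column); this is the
#' discrete Dijkstra-like counterpart of a fast-marching minimal path. Ties
#' break toward smaller column indices.
#'
#' @param weights a [build_weight_image()] result, or a bare non-negative
#'   matrix.
#' @param lambda deviation penalty per column step; default
#'   `0.5 * edge_bonus / d_max` when `weights` carries its parameters.
#' @param d_max maximum per-row column step.
#' @return A `boundary_contour`: tibble `(row, col)` with attributes `cost`
#'   (total path cost) and `lambda`, `d_max`.
#' @export
trace_geodesic_boundary <- function(weights, lambda = NULL, d_max = 2L) {
  if (inherits(weights, "weight_image")) {
    W <- weights$weights
    lambda <- lambda %||% (0.5 * weights$params$edge_bonus / d_max)
  } else {
    W <- weights
    if (is.null(lambda)) stop("`lambda` is required for a bare weight matrix")
  }
  if (!all(is.finite(W)) || any(W < 0)) stop("weights must be finite and >= 0")
  if (nrow(W) < 2L) stop("need at least 2 rows")
  if (lambda < 0) stop("lambda must be >= 0")
  res <- cpp_trace_geodesic(max(W) - W, lambda, as.integer(d_max))
  out <- tibble::tibble(row = seq_len(nrow(W)), col = res$columns)
  attr(out, "cost") <- res$cost
  attr(out, "lambda") <- lambda
  attr(out, "d_max") <- as.integer(d_max)
  class(out) <- c("boundary_contour", class(out))
  out
}

#' Smooth a boundary surface over the 3D stack
#'
#' Separable Gaussian smoothing of the boundary-radius function over
#' (arc row, slice): circular in the row direction (the contour is closed)
#' and reflected at the first/last slice. Output is sub-voxel.
#'
#' @param contours numeric matrix of boundary columns (or radii), rows = arc
#'   samples, columns = slices; a single `boundary_contour` tibble is also
#'   accepted.
#' @param sd_row,sd_slice Gaussian SDs in row and slice units; either may be
#'   0 to skip that direction.
#' @return Numeric matrix of the same shape (or vector for one slice).
#' @export
smooth_boundary_surface <- function(contours, sd_row = 3, sd_slice = 2) {
  single <- FALSE
  if (inherits(contours, "boundary_contour")) {
    contours <- matrix(contours$col, ncol = 1)
    single <- TRUE
  }
  m <- as.matrix(contours)
  if (sd_row > 0) {
    k <- gaussian_kernel(sd_row)
    m <- circular_filter_rows(m, k)
  }
  if (sd_slice > 0 && ncol(m) > 1L) {
    k <- gaussian_kernel(sd_slice)
    m <- t(reflect_filter_rows(t(m), k))
  }
  if (single) m[, 1] else m
}

circular_filter_rows <- function(m, kernel) {
  n <- nrow(m); h <- (length(kernel) - 1L) %/% 2L
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(kernel)) {
    off <- j - 1L - h
    idx <- ((seq_len(n) - 1L + off) %% n) + 1L
    out <- out + kernel[j] * m[idx, , drop = FALSE]
  }
  out
}

reflect_filter_rows <- function(m, kernel) {
  n <- nrow(m); h <- (length(kernel) - 1L) %/% 2L
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(kernel)) {
    off <- j - 1L - h
    idx <- seq_len(n) + off
    if (n == 1L) idx[] <- 1L
    else {
      # whole-sample reflection, folded as often as needed for short stacks
      p <- (idx - 1L) %% (2L * n - 2L)
      p[p >= n] <- 2L * n - 2L - p[p >= n]
      idx <- p + 1L
    }
    out <- out + kernel[j] * m[idx, , drop = FALSE]
  }
  out
}
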