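# Grey-level thresholding and binary texture filtering in the unwrapped
# frame: the wall is separated from paraffin, then everything that is not
# aligned with the (vertical) lamellar direction is removed.

#' Exact Otsu threshold
#'
#' Finds the threshold minimising the within-class variance (equivalently,
#' maximising the between-class variance) exactly over all splits of the
#' sorted sample, rather than over a fixed histogram binning. The returned
#' threshold is the midpoint between the two values flanking the optimal
#' split; ties resolve to the smallest such threshold.
#'
#' @param values numeric vector (or matrix) of grey values.
#' @return The threshold (single number).
#' @export
otsu_threshold <- function(values) {
  v <- sort(as.vector(values))
  v <- v[is.finite(v)]
  n <- length(v)
  if (n < 2L || v[1] == v[n])
    stop("no bimodality: constant (or near-empty) image")
  cs <- cumsum(v); css <- cumsum(v^2)
  i <- seq_len(n - 1L)
  ss1 <- css[i] - cs[i]^2 / i
  n2 <- n - i
  ss2 <- (css[n] - css[i]) - (cs[n] - cs[i])^2 / n2
  wcv <- ss1 + ss2
  valid <- v[i] < v[i + 1L]          # only splits between distinct values
  wcv[!valid] <- Inf
  k <- which.min(wcv)
  (v[k] + v[k + 1L]) / 2
}

#' Threshold the unwrapped wall image
#'
#' Segments tissue from the paraffin background (or bright texture from
#' tissue ground, depending on the image handed in) with a grey-level
#' threshold. `method = "otsu"` uses [otsu_threshold()]; `method = "fixed"`
#' uses `manual_value`. The mask keeps pixels `>=` the threshold and records
#' the threshold used.
#'
#' @param unwrapped numeric matrix (typically an unwrapped wall image).
#' @param method `"otsu"` or `"fixed"`.
#' @param manual_value threshold for `method = "fixed"`.
#' @return A logical matrix with attribute `threshold`.
#' @export
threshold_wall <- function(unwrapped, method = c("otsu", "fixed"),
                           manual_value = NULL) {
  if (inherits(unwrapped, "unwrapped_image")) unwrapped <- unwrapped$image
  if (!all(is.finite(unwrapped))) stop("non-finite pixels in image")
  method <- match.arg(method)
  thr <- switch(method,
                otsu = otsu_threshold(unwrapped),
                fixed = {
                  if (is.null(manual_value))
                    stop("method = \"fixed\" requires `manual_value`")
                  manual_value
                })
  mask <- unwrapped >= thr
  attr(mask, "threshold") <- thr
  mask
}

shift_rows <- function(m, k, fill = FALSE) {
  n <- nrow(m)
  out <- matrix(fill, n, ncol(m))
  if (k >= 0) { if (k < n) out[(1 + k):n, ] <- m[1:(n - k), , drop = FALSE] }
  else { k <- -k; if (k < n) out[1:(n - k), ] <- m[(1 + k):n, , drop = FALSE] }
  out
}

erode_vertical <- function(mask, length_vox) {
  h <- (length_vox - 1L) %/% 2L
  out <- mask
  for (k in setdiff(-h:h, 0L)) out <- out & shift_rows(mask, k, FALSE)
  out
}

dilate_vertical <- function(mask, length_vox) {
  h <- (length_vox - 1L) %/% 2L
  out <- mask
  for (k in setdiff(-h:h, 0L)) out <- out | shift_rows(mask, k, FALSE)
  out
}

#' 1D vertical morphological opening
#'
#' Opening (erosion then dilation) with a vertical line structuring element
#' spanning `length_vox` rows. In the unwrapped frame rows run along the
#' arc, so lamellae -- which are radially thin but circumferentially
#' continuous -- survive, while transverse adventitial features shorter than
#' the element are annihilated.
#'
#' @param mask logical matrix.
#' @param length_vox odd structuring-element length, `>= 3`.
#' @return Logical matrix (a subset of `mask`); the `threshold` attribute of
#'   the input, if any, is preserved.
#' @export
open_vertical <- function(mask, length_vox = 9L) {
  length_vox <- as.integer(length_vox)
  if (length_vox < 3L || length_vox %% 2L == 0L)
    stop("length_vox must be odd and >= 3")
  out <- dilate_vertical(erode_vertical(mask, length_vox), length_vox)
  attr(out, "threshold") <- attr(mask, "threshold")
  out
}

#' Label connected components
#'
#' Connected-component labeling of a binary mask: 8-connectivity for 2D
#' masks, 26-connectivity for 3D masks.
#'
#' @param mask logical matrix or 3D array.
#' @return Integer array of the same shape; 0 is background, components are
#'   numbered from 1.
#' @export
label_components <- function(mask) {
  d <- dim(mask)
  if (is.null(d) || !length(d) %in% 2:3)
    stop("mask must be a 2D matrix or 3D array")
  cpp_label_components(as.vector(mask != 0), d)
}

#' Remove small connected components
#'
#' Deletes 8-connected foreground components with fewer than `min_size_px`
#' pixels (components of exactly `min_size_px` pixels are retained).
#'
#' @param mask logical matrix.
#' @param min_size_px minimum component area, `>= 1`.
#' @return Logical matrix.
#' @export
remove_islands <- function(mask, min_size_px = 25L) {
  if (min_size_px < 1L) stop("min_size_px must be >= 1")
  lab <- cpp_label_components(as.vector(mask), dim(mask))
  if (max(lab) == 0L) return(mask)
  sizes <- tabulate(lab)
  keep <- lab > 0L & sizes[pmax(lab, 1L)] >= min_size_px
  out <- matrix(keep, nrow(mask), ncol(mask))
  attr(out, "threshold") <- attr(mask, "threshold")
  out
}

#' Per-row outermost-edge profile
#'
#' For each row of a (texture-filtered) wall mask, records the column of the
#' outermost segmented pixel; rows with no segmented pixel are flagged
#' missing.
#'
#' @param mask logical matrix in the unwrapped frame.
#' @return Tibble with `row`, `xe` (outermost column, `NA` when missing) and
#'   `missing`.
#' @export
edge_profile <- function(mask) {
  nr <- nrow(mask)
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx)) stop("wall lost: no segmented pixels in any row")
  xe <- rep(NA_integer_, nr)
  agg <- tapply(idx[, 2], idx[, 1], max)
  xe[as.integer(names(agg))] <- as.integer(agg)
  tibble::tibble(row = seq_len(nr), xe = xe, missing = is.na(xe))
}
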