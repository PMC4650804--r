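#' Tomogram objects
#'
#' A tomogram is a 3D greyscale attenuation volume stored as a numeric array
#' indexed `[row, col, slice]` (one trans-axial slice per third-dimension
#' index), together with its isotropic voxel size in micrometres.
#'
#' @param values numeric 3D array (or a matrix, promoted to a single slice).
#' @param voxel_size_um isotropic voxel edge length in micrometres.
#' @param axial_axis array axis running along the vessel; the canonical
#'   layout keeps slices on axis 3 and other inputs are permuted on
#'   construction.
#' @return An object of class `tomogram`: a list with `values`,
#'   `voxel_size_um` and `axial_axis = 3`.
#' @examples
#' tomo <- tomogram(array(runif(8 * 8 * 2), c(8, 8, 2)), voxel_size_um = 0.75)
#' dim(tomo$values)
#' @export
tomogram <- function(values, voxel_size_um, axial_axis = 3L) {
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array (row, col, slice)")
  if (!all(is.finite(values))) stop("tomogram values must be finite")
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1L ||
      voxel_size_um <= 0)
    stop("`voxel_size_um` must be a single positive number")
  axial_axis <- as.integer(axial_axis)
  if (!axial_axis %in% 1:3) stop("`axial_axis` must be 1, 2 or 3")
  if (axial_axis != 3L) {
    perm <- switch(axial_axis, `1` = c(2, 3, 1), `2` = c(1, 3, 2))
    values <- aperm(values, perm)
  }
  structure(list(values = values, voxel_size_um = voxel_size_um,
                 axial_axis = 3L),
            class = "tomogram")
}

#' @export
print.tomogram <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<tomogram> %d x %d x %d voxels, %.3g um/voxel, range [%.3g, %.3g]\n",
              d[1], d[2], d[3], x$voxel_size_um,
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.tomogram <- function(x) dim(x$values)

n_slices <- function(tomo) dim(tomo$values)[3]

as_tomogram <- function(x, voxel_size_um = NULL) {
  if (inherits(x, "tomogram")) return(x)
  tomogram(x, voxel_size_um %||% stop("voxel_size_um required"))
}
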