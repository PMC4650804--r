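# Internal numeric helpers shared across modules.

# Evaluate `expr` under a fixed RNG state, restoring the caller's stream.
with_fixed_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Truncated, renormalised Gaussian kernel with half-width ceiling(4*sigma).
gaussian_kernel <- function(sigma, half_width = max(1L, ceiling(4 * sigma))) {
  x <- seq(-half_width, half_width)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# 1D convolution of an array along one axis with edge replication.
conv1d_axis <- function(arr, kernel, axis) {
  d <- dim(arr)
  if (is.null(d)) d <- length(arr)
  nd <- length(d)
  perm <- c(axis, setdiff(seq_len(nd), axis))
  a <- aperm(arr, perm)
  n <- dim(a)[1]
  m <- matrix(a, nrow = n)
  h <- (length(kernel) - 1L) / 2L
  out <- matrix(0, nrow = n, ncol = ncol(m))
  for (j in seq_along(kernel)) {
    off <- j - 1L - h
    idx <- pmin(pmax(seq_len(n) + off, 1L), n)
    out <- out + kernel[j] * m[idx, , drop = FALSE]
  }
  dim(out) <- dim(a)
  aperm(out, order(perm))
}

# Separable 3D Gaussian blur (the phantom's PSF model).
gaussian_blur3d <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  k <- gaussian_kernel(sigma)
  for (ax in 1:3) arr <- conv1d_axis(arr, k, ax)
  arr
}

# Bilinear interpolation of matrix `img` at (x = col, y = row) positions,
# constant extrapolation outside.  x/y are 1-based voxel-centre coordinates.
bilinear_sample <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  x <- pmin(pmax(x, 1), nc); y <- pmin(pmax(y, 1), nr)
  x0 <- pmin(floor(x), nc - 1L); y0 <- pmin(floor(y), nr - 1L)
  fx <- x - x0; fy <- y - y0
  i00 <- cbind(y0, x0); i10 <- cbind(y0 + 1, x0)
  i01 <- cbind(y0, x0 + 1); i11 <- cbind(y0 + 1, x0 + 1)
  img[i00] * (1 - fx) * (1 - fy) + img[i10] * (1 - fx) * fy +
    img[i01] * fx * (1 - fy) + img[i11] * fx * fy
}

# Periodic linear interpolation of a radius-vs-angle table at query angles.
interp_periodic <- function(theta, value, theta_out) {
  o <- order(theta)
  th <- theta[o]; v <- value[o]
  th <- c(th[length(th)] - 2 * pi, th, th[1] + 2 * pi)
  v <- c(v[length(v)], v, v[1])
  approx(th, v, xout = theta_out, rule = 2)$y
}

`%||%` <- function(a, b) if (is.null(a)) b else a
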