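# Gaussian-mixture model of the per-row candidate boundary positions.
# The values modelled are xe + 1: the first pixel outward of the outermost
# segmented wall pixel in each row, i.e. the candidate media-adventitia
# boundary position. The dominant component's mean is the mean edge
# position used to anchor the geodesic weight image.

#' Fit a Gaussian mixture to the edge-position distribution
#'
#' Runs EM on the values `xe + 1` from an [edge_profile()]. Initialisation
#' is deterministic (component means at the `(2i - 1) / 2k` quantiles, equal
#' weights, pooled SD), so the fit is reproducible without an RNG. The
#' dominant component is the one with the largest weight (ties resolve to
#' the smaller mean); its mean is the mean edge position, and the default
#' closeness tolerance is twice its SD.
#'
#' @param profile tibble from [edge_profile()].
#' @param n_components 1, 2 (default) or 3 mixture components; the second
#'   component absorbs rows corrupted by residual adventitial features.
#' @param tolerance closeness tolerance around the dominant mean; default
#'   `2 * dominant SD`.
#' @param max_iter,tol EM iteration cap and log-likelihood convergence
#'   tolerance.
#' @return An `edge_model`: list with `components` (tibble of weight, mean,
#'   sd), `dominant_mean`, `tolerance`, `loglik`, `n_iter`, `n_obs`.
#' @export
fit_edge_model <- function(profile, n_components = 2L, tolerance = NULL,
                           max_iter = 200L, tol = 1e-8) {
  n_components <- as.integer(n_components)
  if (!n_components %in% 1:3) stop("n_components must be 1, 2 or 3")
  x <- profile$xe[!profile$missing] + 1
  if (length(x) < 10L) stop("need at least 10 defined rows")
  if (length(x) < n_components)
    stop("fewer defined rows than mixture components")
  k <- n_components
  mu <- as.numeric(quantile(x, probs = (2 * seq_len(k) - 1) / (2 * k),
                            type = 7))
  sg <- rep(max(sd(x), 0.5), k)
  if (k == 1L) sg <- max(sd(x), 1e-3)
  w <- rep(1 / k, k)
  var_floor <- 1e-4
  ll_old <- -Inf; it <- 0L
  n <- length(x)
  repeat {
    it <- it + 1L
    dens <- vapply(seq_len(k),
                   function(j) w[j] * dnorm(x, mu[j], sg[j]), numeric(n))
    dens <- matrix(dens, nrow = n)
    rs <- rowSums(dens)
    rs[rs < 1e-300] <- 1e-300
    ll <- sum(log(rs))
    resp <- dens / rs
    nk <- colSums(resp)
    nk[nk < 1e-12] <- 1e-12
    w <- nk / n
    mu <- colSums(resp * x) / nk
    sg <- sqrt(pmax(colSums(resp * (x - rep(mu, each = n))^2) / nk,
                    var_floor))
    if (it >= max_iter || abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  ord <- order(-w, mu)
  comp <- tibble::tibble(weight = w[ord], mean = mu[ord], sd = sg[ord])
  dom <- comp$mean[1]
  structure(list(components = comp,
                 dominant_mean = dom,
                 tolerance = tolerance %||% (2 * comp$sd[1]),
                 loglik = ll, n_iter = it, n_obs = n,
                 n_components = k),
            class = "edge_model")
}

#' @export
print.edge_model <- function(x, ...) {
  cat(sprintf("<edge_model> %d-component GMM of edge positions; mean edge position %.2f (tolerance %.2f)\n",
              x$n_components, x$dominant_mean, x$tolerance))
  print(x$components)
  invisible(x)
}

#' Tidy an edge model
#'
#' @param x an `edge_model`.
#' @param ... unused.
#' @return Tibble with one row per mixture component (`component`, `weight`,
#'   `mean`, `sd`, `dominant`).
#' @export
tidy.edge_model <- function(x, ...) {
  dplyr::mutate(x$components,
                component = dplyr::row_number(),
                dominant = dplyr::row_number() == 1L,
                .before = 1L)
}

#' One-row summary of an edge model
#'
#' @param x an `edge_model`.
#' @param ... unused.
#' @return Tibble with `n_components`, `dominant_mean`, `tolerance`,
#'   `loglik`, `n_iter`, `n_obs`.
#' @export
glance.edge_model <- function(x, ...) {
  tibble::tibble(n_components = x$n_components,
                 dominant_mean = x$dominant_mean,
                 tolerance = x$tolerance,
                 loglik = x$loglik, n_iter = x$n_iter, n_obs = x$n_obs)
}
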