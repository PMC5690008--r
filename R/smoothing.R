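# Locally adaptive smoothing of Monte Carlo scatter projections.
#
# Scatter distributions vary slowly across the detector, so large smoothing
# windows are statistically admissible almost everywhere; near genuine
# gradients a large window would bias the estimate. The smoother below fits
# a quadratic 2D polynomial (Savitzky-Golay) in square windows of growing
# half-width and keeps, per pixel, the largest window whose residuals are
# chi-square consistent with the per-pixel statistical uncertainties.

# center-value Savitzky-Golay kernel for a (2h+1)^2 window, quadratic basis
.sg_kernel <- function(h) {
  g <- seq(-h, h)
  X <- expand.grid(x = g, y = g)
  B <- cbind(1, X$x, X$y, X$x^2, X$y^2, X$x * X$y)
  K <- solve(crossprod(B), t(B))[1, ]
  matrix(K, 2 * h + 1, 2 * h + 1)
}

#' Locally adaptive smoothing of a scatter projection
#'
#' Smooths a Monte Carlo scatter image with quadratic local-polynomial
#' (Savitzky-Golay) fits, choosing per pixel the largest square window whose
#' residuals remain statistically consistent with the pixel uncertainties
#' (`chi2/n <= 1 + consistency_k * sqrt(2/n)`). The propagated relative
#' uncertainty of the smoothed value is returned. A noiseless image
#' (all-zero `rel_uncertainty`) is returned unchanged.
#'
#' @param scatter a [projection_image] with `rel_uncertainty` present.
#' @param max_halfwidth largest window half-width tried (window
#'   `(2h+1) x (2h+1)` pixels).
#' @param consistency_k tolerance multiplier of the chi-square consistency
#'   test (larger = more aggressive smoothing).
#' @return smoothed [projection_image] with updated `rel_uncertainty`.
#' @export
adaptive_smooth <- function(scatter, max_halfwidth = 8, consistency_k = 3) {
  stopifnot(inherits(scatter, "projection_image"))
  if (is.null(scatter$rel_uncertainty))
    stop("adaptive_smooth requires a rel_uncertainty map")
  y <- scatter$pixels
  sig <- scatter$rel_uncertainty * abs(y)
  if (all(sig == 0)) return(scatter)
  # the per-pixel batch sigma estimates are themselves noisy (and zero in
  # sparsely hit pixels); stabilize by local averaging of the variance map
  sig2 <- cpp_conv2_same(sig^2, matrix(1 / 25, 5, 5))
  floor_sig <- stats::median(sqrt(sig2[sig2 > 0]))
  sig <- pmax(sqrt(sig2), floor_sig * 0.2)
  hs <- unique(pmin(2^(0:10), max_halfwidth))
  hs <- hs[hs >= 1]
  best <- y
  bestvar <- sig^2
  chosen <- matrix(0L, nrow(y), ncol(y))
  for (h in hs) {
    K <- .sg_kernel(h)
    s <- cpp_conv2_same(y, K)
    n <- (2 * h + 1)^2
    z2 <- ((y - s) / sig)^2
    box <- matrix(1 / n, 2 * h + 1, 2 * h + 1)
    stat <- cpp_conv2_same(z2, box)
    # expected residual variance factor of the centered fit: 1 - 2K0 + |K|^2
    efac <- 1 - 2 * K[h + 1, h + 1] + sum(K^2)
    ok <- stat <= efac * (1 + consistency_k * sqrt(2 / n))
    v <- cpp_conv2_same(sig^2, K^2)
    upd <- ok & (v < bestvar)
    best[upd] <- s[upd]
    bestvar[upd] <- v[upd]
    chosen[upd] <- h
  }
  rel <- ifelse(abs(best) > 0, sqrt(pmax(bestvar, 0)) / abs(best), 0)
  out <- projection_image(pmax(best, 0), scatter$component, scatter$angle,
                          rel_uncertainty = rel)
  attr(out, "window_halfwidth") <- chosen
  out
}
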