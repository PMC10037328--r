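#' Empirical semivariogram
#'
#' \deqn{\hat\gamma(h) = \frac{1}{2 N(h)} \sum_{(i,j)\in h} (z_i - z_j)^2}
#' over equal-width distance bins spanning \eqn{[0, \max d / 2]} (20 bins by
#' default, the standard binning); empty bins are dropped.
#'
#' @param coords n-by-2 matrix of projected coordinates (meters), n >= 10.
#' @param values numeric site values.
#' @param nBins number of equal-width bins (default 20).
#' @return data.frame with \code{center}, \code{gamma}, \code{npairs} per
#'   nonempty bin, with the bin edges attached as attribute \code{"edges"}.
#' @export
empiricalVariogram <- function(coords, values, nBins = 20) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 10L) stop("need at least 10 sites")
  if (length(values) != n) stop("length(values) must match coords")
  d <- as.numeric(dist(coords))
  dz2 <- as.numeric(dist(matrix(values, ncol = 1)))^2
  maxLag <- max(d) / 2
  keep <- d <= maxLag
  if (sum(keep) < 2L) stop("fewer than 2 pairs within the lag cutoff")
  edges <- seq(0, maxLag, length.out = nBins + 1L)
  bin <- findInterval(d[keep], edges, rightmost.closed = TRUE)
  bin[bin < 1L] <- 1L
  g  <- tapply(dz2[keep], bin, function(v) mean(v) / 2)
  ct <- tapply(dz2[keep], bin, length)
  ce <- (edges[-1] + edges[-length(edges)]) / 2
  idx <- as.integer(names(g))
  out <- data.frame(center = ce[idx], gamma = as.numeric(g),
                    npairs = as.numeric(ct))
  attr(out, "edges") <- edges
  out
}

#' Fit an exponential variogram model
#'
#' Weighted least squares (weights = pair counts per bin) of
#' \eqn{\gamma(h) = c_0 + c\,(1 - e^{-h/\ell})} to the empirical bins, with
#' bounds \eqn{c_0 \ge 0}, \eqn{c > 0}, \eqn{\ell \in (0, 10\,h_{max}]}.
#' \code{length} in the result is the length-scale parameter \eqn{\ell};
#' the effective range of the exponential model is \eqn{3\ell}.
#'
#' A fit that degenerates — vanishing partial sill, or a length scale pinned
#' at a bound so the curve is indistinguishable from a constant over the
#' observed lags — raises the \code{flat} flag: the variogram carries no
#' usable spatial structure and kriging from it is not meaningful
#' (deterministic interpolation is the fallback).
#'
#' @param emp empirical variogram data.frame from [empiricalVariogram()]
#'   (needs >= 4 nonempty bins).
#' @return A [VariogramModel-class].
#' @export
fitExponentialVariogram <- function(emp) {
  if (nrow(emp) < 4L) stop("need at least 4 nonempty bins")
  h <- emp$center; g <- emp$gamma; cnt <- emp$npairs
  maxLag <- max(h)
  gbar <- sum(g * cnt) / sum(cnt)
  start <- c(nugget = max(min(g) / 2, 1e-8),
             sill = max(gbar - min(g) / 2, 1e-8),
             ell = maxLag / 3)
  lower <- c(0, 1e-12, maxLag * 1e-6)
  upper <- c(Inf, Inf, 10 * maxLag)
  resid <- function(p) sqrt(cnt) * (g - (p[1] + p[2] * (1 - exp(-h / p[3]))))
  fit <- minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                            fn = resid,
                            control = minpack.lm::nls.lm.control(
                              ftol = 1e-12, ptol = 1e-12, maxiter = 500))
  if (!(fit$info %in% 1:4))
    stop(sprintf(
      "variogram fit did not converge (info %d); last iterate: nugget=%.4g sill=%.4g length=%.4g",
      fit$info, fit$par[1], fit$par[2], fit$par[3]))
  p <- unname(fit$par)
  ## flat variogram: no resolvable spatial structure over the observed lags
  atUpper <- p[3] >= 0.99 * upper[3]
  relSill <- p[2] / max(p[1] + p[2], .Machine$double.eps)
  resolved <- p[2] * (1 - exp(-maxLag / p[3]))  # rise of the curve in-range
  flat <- relSill < 0.05 ||
    resolved < 0.05 * max(gbar, .Machine$double.eps) ||
    p[3] < min(h) / 2 ||                  # sub-resolution scale: pure nugget
    (atUpper && resolved < 0.2 * gbar)
  if (flat)
    warning("flat variogram: no spatial structure detected; kriging from this model is not meaningful")
  new("VariogramModel", binCenters = h, gammaHat = g, counts = cnt,
      nugget = p[1], sill = p[2], length = p[3],
      flat = flat, converged = TRUE)
}

## model semivariance at distances h
.gammaModel <- function(model, h) {
  model@nugget * (h > 0) + model@sill * (1 - exp(-h / model@length))
}
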