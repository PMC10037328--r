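#' Adaptive triangular-kernel spatial weights
#'
#' Builds the kernel weights \eqn{w_{ij} = \max(0, 1 - d_{ij}/h_i)} with an
#' adaptive per-site bandwidth \eqn{h_i} equal to the exact Euclidean
#' distance to the k-th nearest neighbour of site i (k = 7 by default, the
#' conventional nearest-point bandwidth).  The diagonal is zero; a site at
#' exactly the bandwidth distance gets weight 0; asymmetric weights
#' \eqn{w_{ij} \ne w_{ji}} are expected, as adaptive bandwidths produce.
#' Rows are optionally scaled to sum to one (the default, matching the usual
#' spatial-econometrics convention for Moran statistics).
#'
#' @param coords n-by-2 matrix of projected coordinates (meters).
#' @param k neighbour count defining the bandwidth (default 7); requires
#'   n > k.
#' @param kernel only \code{"triangular"}.
#' @param rowStandardize scale each nonzero row to sum 1 (default TRUE).
#' @return A [SpatialWeights-class].
#' @export
kernelWeights <- function(coords, k = 7, kernel = "triangular",
                          rowStandardize = TRUE) {
  kernel <- match.arg(kernel, "triangular")
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n <= k) stop("need more sites than k")
  d <- as.matrix(dist(coords))
  offDiag <- d + diag(Inf, n)
  if (min(offDiag) <= 0) {
    pair <- which(offDiag <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf("duplicate coordinates: sites %d and %d coincide",
                 pair[1], pair[2]))
  }
  ii <- jj <- integer(0); ww <- numeric(0)
  for (i in seq_len(n)) {
    di <- offDiag[i, ]
    h <- sort(di)[k]
    w <- pmax(0, 1 - di / h)
    nz <- which(w > 0)
    ii <- c(ii, rep(i, length(nz))); jj <- c(jj, nz); ww <- c(ww, w[nz])
  }
  if (rowStandardize) {
    rs <- tapply(ww, ii, sum)
    ww <- ww / rs[as.character(ii)]
  }
  new("SpatialWeights", i = as.integer(ii), j = as.integer(jj),
      w = as.numeric(ww), n = as.integer(n), k = as.integer(k),
      kernel = kernel, rowStandardized = rowStandardize)
}
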