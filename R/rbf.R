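#' Thin-plate-spline radial-basis interpolation
#'
#' Exact deterministic interpolant through all data points using the
#' thin-plate radial kernel \eqn{\phi(r) = r^2 \log r} with an affine
#' polynomial term, the standard choice when the variogram carries no
#' usable structure and kriging is not applicable.  Affine data are
#' reproduced exactly everywhere.
#'
#' @param coords n-by-2 matrix of data coordinates (>= 3 non-collinear
#'   points).
#' @param values numeric data values.
#' @param grid evaluation locations (matrix with 2 columns); default a
#'   100 x 100 [makeGrid()] with 5\% margin.
#' @return data.frame with \code{easting}, \code{northing},
#'   \code{prediction}.
#' @export
rbfInterpolate <- function(coords, values, grid = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 3L) stop("need at least 3 points")
  if (length(values) != n) stop("length(values) must match coords")
  if (is.null(grid)) grid <- makeGrid(coords)
  grid <- as.matrix(grid)
  ## center coordinates: TPS is translation invariant but the augmented
  ## system is badly conditioned at raw UTM magnitudes (northing ~ 1e6 m)
  ctr <- colMeans(coords)
  coordsC <- sweep(coords, 2, ctr)
  gridC <- sweep(grid[, 1:2, drop = FALSE], 2, ctr)
  tps <- function(r) ifelse(r > 0, r^2 * log(r), 0)
  K <- tps(as.matrix(dist(coordsC)))
  P <- cbind(1, coordsC)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  rhs <- c(values, numeric(3))
  sol <- tryCatch(solve(A, rhs), error = function(e)
    stop("singular thin-plate system (collinear or duplicate points): ",
         conditionMessage(e)))
  wts <- sol[seq_len(n)]; poly <- sol[n + 1:3]
  d0 <- sqrt(outer(gridC[, 1], coordsC[, 1], "-")^2 +
             outer(gridC[, 2], coordsC[, 2], "-")^2)
  pred <- as.numeric(tps(d0) %*% wts) + poly[1] +
    poly[2] * gridC[, 1] + poly[3] * gridC[, 2]
  data.frame(easting = grid[, 1], northing = grid[, 2], prediction = pred)
}
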