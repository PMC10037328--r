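#' Regular prediction grid over the data bounding box
#'
#' @param coords n-by-2 matrix of projected coordinates.
#' @param nx,ny nodes per axis (default 100).
#' @param margin fractional bounding-box margin (default 0.05).
#' @return matrix with columns \code{easting}, \code{northing}
#'   (nx * ny rows), with \code{nx}, \code{ny} attached as attributes.
#' @export
makeGrid <- function(coords, nx = 100, ny = 100, margin = 0.05) {
  coords <- as.matrix(coords)
  rx <- range(coords[, 1]); ry <- range(coords[, 2])
  mx <- margin * diff(rx); my <- margin * diff(ry)
  gx <- seq(rx[1] - mx, rx[2] + mx, length.out = nx)
  gy <- seq(ry[1] - my, ry[2] + my, length.out = ny)
  g <- as.matrix(expand.grid(easting = gx, northing = gy))
  attr(g, "nx") <- nx; attr(g, "ny") <- ny
  g
}

#' Ordinary kriging from a fitted exponential variogram
#'
#' At each grid node solves the ordinary-kriging system in semivariance
#' form: the data-to-data semivariance matrix augmented with the
#' unbiasedness row/column of ones, right-hand side the data-to-node
#' semivariances.  Predictions are \eqn{\sum_i \lambda_i z_i} with
#' \eqn{\sum_i \lambda_i = 1}; the kriging variance
#' \eqn{\sigma^2 = \lambda^\top \gamma_0 + \mu} is reported.  With a zero
#' nugget the predictor interpolates the data exactly.
#'
#' @param coords n-by-2 matrix of data coordinates (meters).
#' @param values numeric data values.
#' @param model a fitted [VariogramModel-class] (refused if flagged flat).
#' @param grid prediction locations (matrix with 2 columns); default a
#'   100 x 100 [makeGrid()] with 5\% margin.
#' @return data.frame with \code{easting}, \code{northing},
#'   \code{prediction}, \code{variance}; the kriging weight matrix
#'   (nodes x data) is attached as attribute \code{"lambda"}.
#' @export
ordinaryKrige <- function(coords, values, model, grid = NULL) {
  stopifnot(is(model, "VariogramModel"))
  if (model@flat)
    stop("flat variogram model: kriging is not meaningful; use rbfInterpolate")
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (length(values) != n) stop("length(values) must match coords")
  if (is.null(grid)) grid <- makeGrid(coords)
  grid <- as.matrix(grid)
  D <- as.matrix(dist(coords))
  if (n > 1 && min(D + diag(Inf, n)) <= 0)
    stop("duplicate data points make the kriging system singular")
  G <- .gammaModel(model, D)
  A <- rbind(cbind(G, 1), c(rep(1, n), 0))
  ## data-to-node semivariances for all nodes at once
  d0 <- sqrt(outer(grid[, 1], coords[, 1], "-")^2 +
             outer(grid[, 2], coords[, 2], "-")^2)
  B <- rbind(t(.gammaModel(model, d0)), 1)          # (n+1) x nNodes
  sol <- tryCatch(solve(A, B), error = function(e)
    stop("singular kriging system: ", conditionMessage(e)))
  lambda <- t(sol[seq_len(n), , drop = FALSE])      # nodes x n
  mu <- sol[n + 1L, ]
  pred <- as.numeric(lambda %*% values)
  varK <- rowSums(lambda * .gammaModel(model, d0)) + mu
  out <- data.frame(easting = grid[, 1], northing = grid[, 2],
                    prediction = pred, variance = pmax(varK, 0))
  attr(out, "lambda") <- lambda
  out
}
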