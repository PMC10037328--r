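#' Construct a field specification
#'
#' Convenience constructor for [FieldSpec-class]; see that class for the
#' meaning of each parameter.  Defaults describe a hectare-scale field
#' sampled at a few dozen positions with a 3 m GPS error, the typical
#' hand-held-receiver accuracy of georeferenced field sampling.
#'
#' @param nSites number of sampling positions (>= 3).
#' @param extentM numeric(2): field width and height in meters.
#' @param corrLengthM exponential correlation length in meters.
#' @param sill partial sill (spatially correlated variance).
#' @param nugget nugget variance.
#' @param mean field mean.
#' @param originDeg (lat, lon) of the field origin, decimal degrees WGS84.
#' @param gpsSigmaM GPS jitter standard deviation in meters (default 3).
#' @param seed integer seed.
#' @return A validated [FieldSpec-class].
#' @examples
#' fieldSpec(nSites = 60, extentM = c(500, 200), corrLengthM = 30, seed = 1)
#' @export
fieldSpec <- function(nSites, extentM = c(500, 200), corrLengthM = 30,
                      sill = 1, nugget = 0.1, mean = 0,
                      originDeg = c(40.82, 16.08), gpsSigmaM = 3,
                      seed = 1L) {
  if (any(extentM <= 0)) stop("extentM must be positive")
  new("FieldSpec", nSites = as.integer(nSites), extentM = as.numeric(extentM),
      corrLengthM = as.numeric(corrLengthM), sill = as.numeric(sill),
      nugget = as.numeric(nugget), mean = as.numeric(mean),
      originDeg = as.numeric(originDeg), gpsSigmaM = as.numeric(gpsSigmaM),
      seed = as.integer(seed))
}

#' Construct a bimodal-mixture specification
#'
#' @param modeLo,modeHi the two mode centers (modeLo < modeHi).
#' @param fracHi fraction of sites in the high mode, in (0, 1).
#' @param clusterLengthM correlation length of the latent membership field.
#' @return A validated [BimodalSpec-class].
#' @export
bimodalSpec <- function(modeLo = -0.5, modeHi = 2.0, fracHi = 0.3,
                        clusterLengthM = 100) {
  new("BimodalSpec", modeLo = as.numeric(modeLo), modeHi = as.numeric(modeHi),
      fracHi = as.numeric(fracHi), clusterLengthM = as.numeric(clusterLengthM))
}

## meters per degree of latitude / longitude at the field origin; jitter is
## a few meters so the local flat-earth metric is ample
.metersPerDegree <- function(latDeg) {
  c(lat = 111320, lon = 111320 * cos(latDeg * pi / 180))
}

#' Sample georeferenced field positions on a jittered quasi-grid
#'
#' Lays \code{nSites} positions on a regular grid spanning the field extent
#' (grid aspect matched to the extent), then jitters each position with
#' isotropic Gaussian noise of standard deviation \code{gpsSigmaM}, emulating
#' the GPS error of georeferenced sampling.  Jitter is converted from meters
#' to degrees with the local metric at the field origin.
#'
#' @param spec a [FieldSpec-class].
#' @return data.frame with columns \code{id}, \code{lat}, \code{lon}
#'   (degrees) and the grid offsets \code{x}, \code{y} in meters before
#'   jitter is applied to the degree coordinates.
#' @export
samplePositions <- function(spec) {
  stopifnot(is(spec, "FieldSpec"))
  validObject(spec)
  n <- spec@nSites
  w <- spec@extentM[1]; h <- spec@extentM[2]
  nx <- max(1L, round(sqrt(n * w / h)))
  ny <- ceiling(n / nx)
  while (nx * ny < n) nx <- nx + 1L
  gx <- if (nx == 1L) w / 2 else seq(0, w, length.out = nx)
  gy <- if (ny == 1L) h / 2 else seq(0, h, length.out = ny)
  grid <- expand.grid(x = gx, y = gy)[seq_len(n), ]
  set.seed(spec@seed)
  jx <- rnorm(n, 0, spec@gpsSigmaM)
  jy <- rnorm(n, 0, spec@gpsSigmaM)
  mpd <- .metersPerDegree(spec@originDeg[1])
  data.frame(
    id  = seq_len(n),
    lat = spec@originDeg[1] + (grid$y + jy) / mpd["lat"],
    lon = spec@originDeg[2] + (grid$x + jx) / mpd["lon"],
    x   = grid$x, y = grid$y,
    row.names = NULL)
}

## dense covariance factorization for a stationary exponential GRF
.grfCovariance <- function(coords, sill, nugget, ell) {
  d <- as.matrix(dist(coords))
  C <- sill * exp(-d / ell)
  diag(C) <- diag(C) + nugget
  C
}

#' Simulate a Gaussian random field with exponential covariance
#'
#' Draws one realization of the stationary Gaussian field with covariance
#' \eqn{C(h) = \mathrm{sill}\, e^{-h/\ell}} plus a nugget on the diagonal, at
#' the given projected site coordinates, by Cholesky factorization of the
#' dense site-covariance matrix (exact at the desk scale of a few hundred
#' sites).
#'
#' @param coords n-by-2 matrix of projected coordinates in meters.
#' @param spec a [FieldSpec-class] supplying sill, nugget, correlation
#'   length, mean and seed.
#' @param seed optional seed overriding \code{spec@seed}.
#' @return numeric vector of site values.
#' @export
simulateGRF <- function(coords, spec, seed = NULL) {
  stopifnot(is(spec, "FieldSpec"))
  coords <- as.matrix(coords)
  if (nrow(coords) < 2L) stop("need at least 2 positions")
  C <- .grfCovariance(coords, spec@sill, spec@nugget, spec@corrLengthM)
  L <- tryCatch(chol(C), error = function(e) {
    ev <- min(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
    stop(sprintf(
      "site covariance matrix is not positive definite (min eigenvalue %.3g); increase the nugget",
      ev))
  })
  set.seed(if (is.null(seed)) spec@seed else seed)
  z <- rnorm(nrow(coords))
  as.numeric(spec@mean + crossprod(L, z))
}

#' Simulate a spatially clustered bimodal field
#'
#' A latent Gaussian random field with correlation length
#' \code{bspec@clusterLengthM} (unit sill, no nugget) is thresholded at its
#' empirical \code{1 - fracHi} quantile: sites above the threshold are
#' assigned to \code{modeHi}, the rest to \code{modeLo}.  Observation noise
#' with variance \code{spec@nugget} is added on top, so the output histogram
#' shows two modes whose spread is set by the nugget.
#'
#' @param coords n-by-2 matrix of projected coordinates in meters.
#' @param spec a [FieldSpec-class] (supplies the nugget-scaled noise and the
#'   seed).
#' @param bspec a [BimodalSpec-class].
#' @param seed optional seed overriding \code{spec@seed}.
#' @return list with \code{values} (numeric vector) and \code{membership}
#'   (logical, TRUE = high mode).
#' @export
simulateBimodalField <- function(coords, spec, bspec, seed = NULL) {
  stopifnot(is(spec, "FieldSpec"), is(bspec, "BimodalSpec"))
  validObject(bspec)
  coords <- as.matrix(coords)
  n <- nrow(coords)
  latentSpec <- fieldSpec(
    nSites = max(3L, n), extentM = spec@extentM,
    corrLengthM = bspec@clusterLengthM, sill = 1, nugget = 1e-8,
    mean = 0, originDeg = spec@originDeg, gpsSigmaM = spec@gpsSigmaM,
    seed = spec@seed)
  useSeed <- if (is.null(seed)) spec@seed else seed
  latent <- simulateGRF(coords, latentSpec, seed = useSeed)
  thr <- quantile(latent, 1 - bspec@fracHi, names = FALSE, type = 7)
  hi <- latent > thr
  set.seed(useSeed + 1L)
  noise <- rnorm(n, 0, sqrt(spec@nugget))
  vals <- ifelse(hi, bspec@modeHi, bspec@modeLo) + noise
  list(values = vals, membership = hi)
}
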