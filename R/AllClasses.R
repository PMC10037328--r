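#' @import methods
#' @importFrom stats fft rnorm runif quantile sd var dist density qnorm
#'   optim setNames median complete.cases
#' @importFrom utils head read.csv write.csv
NULL

## ---------------------------------------------------------------------------
## Synthetic-field specifications
## ---------------------------------------------------------------------------

#' Specification of a synthetic georeferenced metabolite field
#'
#' Holds the sampling-design and covariance parameters for simulating a
#' stationary Gaussian random field with exponential covariance
#' \eqn{C(h) = \mathrm{sill}\,e^{-h/\ell}} (plus a nugget on the diagonal)
#' over a jittered quasi-grid of field positions.
#'
#' @slot nSites number of sampling positions.
#' @slot extentM numeric(2), field width and height in meters.
#' @slot corrLengthM exponential correlation length \eqn{\ell} in meters.
#' @slot sill partial sill (variance) of the spatial component.
#' @slot nugget nugget variance (uncorrelated component).
#' @slot mean field mean.
#' @slot originDeg numeric(2), (latitude, longitude) of the field origin in
#'   decimal degrees (WGS84).
#' @slot gpsSigmaM standard deviation of the GPS position jitter in meters.
#' @slot seed integer seed making every draw reproducible.
#'
#' @seealso [fieldSpec()], [samplePositions()], [simulateGRF()]
#' @exportClass FieldSpec
setClass("FieldSpec",
  representation(
    nSites      = "integer",
    extentM     = "numeric",
    corrLengthM = "numeric",
    sill        = "numeric",
    nugget      = "numeric",
    mean        = "numeric",
    originDeg   = "numeric",
    gpsSigmaM   = "numeric",
    seed        = "integer"
  )
)

setValidity("FieldSpec", function(object) {
  msg <- character()
  if (object@nSites < 3L) msg <- c(msg, "nSites must be >= 3")
  if (length(object@extentM) != 2L || any(object@extentM <= 0))
    msg <- c(msg, "extentM must be two positive lengths (width, height)")
  if (object@corrLengthM <= 0) msg <- c(msg, "corrLengthM must be > 0")
  if (object@sill < 0) msg <- c(msg, "sill must be >= 0")
  if (object@nugget < 0) msg <- c(msg, "nugget must be >= 0")
  if (object@nugget + object@sill <= 0)
    msg <- c(msg, "nugget + sill must be > 0")
  if (length(object@originDeg) != 2L || abs(object@originDeg[1]) > 90)
    msg <- c(msg, "originDeg must be (lat, lon) with |lat| <= 90")
  if (object@gpsSigmaM < 0) msg <- c(msg, "gpsSigmaM must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Specification of a spatially clustered bimodal mixture
#'
#' Parameters of the two-mode construction used to emulate markedly bimodal
#' metabolite distributions: a latent Gaussian random field with correlation
#' length \code{clusterLengthM} is thresholded at the \code{1 - fracHi}
#' quantile so that a spatially clustered fraction \code{fracHi} of the sites
#' is assigned to the high mode.
#'
#' @slot modeLo center of the low mode.
#' @slot modeHi center of the high mode.
#' @slot fracHi fraction of sites assigned to the high mode, in (0, 1).
#' @slot clusterLengthM correlation length of the latent membership field (m).
#'
#' @seealso [bimodalSpec()], [simulateBimodalField()]
#' @exportClass BimodalSpec
setClass("BimodalSpec",
  representation(
    modeLo         = "numeric",
    modeHi         = "numeric",
    fracHi         = "numeric",
    clusterLengthM = "numeric"
  )
)

setValidity("BimodalSpec", function(object) {
  msg <- character()
  if (object@modeLo >= object@modeHi) msg <- c(msg, "modeLo must be < modeHi")
  if (object@fracHi <= 0 || object@fracHi >= 1)
    msg <- c(msg, "fracHi must be in (0, 1)")
  if (object@clusterLengthM <= 0) msg <- c(msg, "clusterLengthM must be > 0")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## NMR containers
## ---------------------------------------------------------------------------

#' Acquisition parameters of a 1D NMR experiment
#'
#' @slot spectrometerFreqMHz proton Larmor frequency in MHz (e.g. 600.13).
#' @slot sweepWidthHz spectral width in Hz.
#' @slot nPoints number of acquired complex time-domain points.
#' @slot carrierPpm chemical shift of the transmitter (axis center), ppm.
#'
#' @seealso [acquisitionParams()]
#' @exportClass AcquisitionParams
setClass("AcquisitionParams",
  representation(
    spectrometerFreqMHz = "numeric",
    sweepWidthHz        = "numeric",
    nPoints             = "integer",
    carrierPpm          = "numeric"
  )
)

setValidity("AcquisitionParams", function(object) {
  msg <- character()
  if (object@spectrometerFreqMHz <= 0)
    msg <- c(msg, "spectrometerFreqMHz must be > 0")
  if (object@sweepWidthHz <= 0) msg <- c(msg, "sweepWidthHz must be > 0")
  if (object@nPoints < 2L) msg <- c(msg, "nPoints must be >= 2")
  if (length(msg)) msg else TRUE
})

#' Free induction decay
#'
#' The raw complex time-domain NMR signal together with its acquisition
#' parameters.  Sample \eqn{k} is taken at \eqn{t_k = k/\mathrm{sw}} starting
#' from \eqn{t_0 = 0}.
#'
#' @slot signal complex vector of time-domain samples.
#' @slot acq an [AcquisitionParams-class] object.
#'
#' @exportClass FID
setClass("FID",
  representation(signal = "complex", acq = "AcquisitionParams")
)

setValidity("FID", function(object) {
  if (length(object@signal) != object@acq@nPoints)
    "length(signal) must equal acq@nPoints" else TRUE
})

#' Frequency-domain NMR spectrum on a ppm axis
#'
#' The complex spectrum after Fourier transformation; \code{intensity()}
#' returns the real (absorption) part.  The ppm axis is stored monotone
#' decreasing, the plotting convention of 1H spectra.
#'
#' @slot ppm monotone decreasing chemical-shift axis (ppm).
#' @slot signal complex spectral values, same length as \code{ppm}.
#' @slot calibrated has the axis been referenced to DSS?
#' @slot referencePpm the reference chemical shift used for calibration
#'   (0.015 ppm for DSS).
#' @slot acq the acquisition parameters the spectrum was derived from.
#'
#' @exportClass NMRSpectrum
setClass("NMRSpectrum",
  representation(
    ppm          = "numeric",
    signal       = "complex",
    calibrated   = "logical",
    referencePpm = "numeric",
    acq          = "AcquisitionParams"
  )
)

setValidity("NMRSpectrum", function(object) {
  msg <- character()
  if (length(object@ppm) != length(object@signal))
    msg <- c(msg, "ppm and signal must have equal length")
  if (length(object@ppm) > 1 && any(diff(object@ppm) >= 0))
    msg <- c(msg, "ppm axis must be strictly decreasing")
  if (length(msg)) msg else TRUE
})

#' Catalog of quantified NMR signals
#'
#' One row per quantified resonance: compound name, chemical shift of the
#' multiplet center, the multiplet shape code (\code{"s"} singlet, \code{"d"}
#' doublet, \code{"dd"} doublet of doublets, \code{"5m"} 1:4:6:4:1 quintet)
#' and, optionally, the J coupling(s) in Hz.
#'
#' @slot entries data.frame with columns \code{compound}, \code{shift_ppm},
#'   \code{shape} and list-column \code{j_hz}.
#'
#' @seealso [signalCatalog()]
#' @exportClass SignalCatalog
setClass("SignalCatalog", representation(entries = "data.frame"))

setValidity("SignalCatalog", function(object) {
  e <- object@entries
  msg <- character()
  need <- c("compound", "shift_ppm", "shape")
  if (!all(need %in% names(e)))
    return("entries needs columns compound, shift_ppm, shape")
  if (nrow(e) > 1 && any(diff(e$shift_ppm) <= 0))
    msg <- c(msg, "shift_ppm must be strictly increasing within a catalog")
  if (!all(e$shape %in% c("s", "d", "dd", "5m")))
    msg <- c(msg, "shape codes restricted to s, d, dd, 5m")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Geostatistics containers
## ---------------------------------------------------------------------------

#' Georeferenced site-by-variable dataset
#'
#' @slot sites data.frame with columns \code{id}, \code{lat}, \code{lon}
#'   (decimal degrees, WGS84) and \code{easting}, \code{northing}
#'   (meters, transverse Mercator).
#' @slot values numeric matrix, sites in rows, variables (metabolites) in
#'   columns.
#'
#' @seealso [geoDataset()], [projectToUTM()]
#' @exportClass GeoDataset
setClass("GeoDataset",
  representation(sites = "data.frame", values = "matrix")
)

setValidity("GeoDataset", function(object) {
  msg <- character()
  need <- c("id", "lat", "lon", "easting", "northing")
  if (!all(need %in% names(object@sites)))
    return("sites needs columns id, lat, lon, easting, northing")
  if (nrow(object@sites) != nrow(object@values))
    msg <- c(msg, "sites and values must have the same number of rows")
  xy <- as.matrix(object@sites[, c("easting", "northing")])
  if (nrow(xy) > 1 && min(dist(xy)) <= 0)
    msg <- c(msg, "duplicate coordinates (min pairwise distance must be > 0)")
  if (length(msg)) msg else TRUE
})

#' Adaptive triangular-kernel spatial weights
#'
#' Sparse (i, j, w) representation of the kernel weights
#' \eqn{w_{ij} = \max(0, 1 - d_{ij}/h_i)} with per-site adaptive bandwidth
#' \eqn{h_i} equal to the distance to the k-th nearest neighbour.  Because
#' the bandwidth is adaptive the matrix is in general asymmetric.
#'
#' @slot i,j integer site indices of the nonzero weights.
#' @slot w the weights.
#' @slot n number of sites.
#' @slot k neighbour count defining the bandwidth.
#' @slot kernel kernel name (only \code{"triangular"}).
#' @slot rowStandardized were rows scaled to sum to one?
#'
#' @seealso [kernelWeights()], [weightsMatrix()]
#' @exportClass SpatialWeights
setClass("SpatialWeights",
  representation(
    i = "integer", j = "integer", w = "numeric",
    n = "integer", k = "integer", kernel = "character",
    rowStandardized = "logical"
  )
)

setValidity("SpatialWeights", function(object) {
  msg <- character()
  if (length(object@i) != length(object@j) ||
      length(object@i) != length(object@w))
    return("i, j, w must have equal length")
  if (any(object@i == object@j)) msg <- c(msg, "diagonal weights must be absent")
  if (any(object@w < 0)) msg <- c(msg, "weights must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Empirical variogram with a fitted exponential model
#'
#' Bins of the empirical semivariogram
#' \eqn{\hat\gamma(h) = \frac{1}{2N(h)}\sum (z_i - z_j)^2} together with the
#' weighted-least-squares fit of the exponential model
#' \eqn{\gamma(h) = \mathrm{nugget} + \mathrm{sill}(1 - e^{-h/\ell})}.
#' \code{length} is the correlation-length parameter \eqn{\ell}; the
#' effective range of the exponential model is \eqn{3\ell}.
#'
#' @slot binCenters,gammaHat,counts the empirical bins.
#' @slot nugget,sill,length fitted parameters.
#' @slot flat no-spatial-structure flag: the fit degenerated (flat variogram),
#'   so kriging from this model is not meaningful.
#' @slot converged did the optimizer report convergence?
#'
#' @seealso [empiricalVariogram()], [fitExponentialVariogram()]
#' @exportClass VariogramModel
setClass("VariogramModel",
  representation(
    binCenters = "numeric", gammaHat = "numeric", counts = "numeric",
    nugget = "numeric", sill = "numeric", length = "numeric",
    flat = "logical", converged = "logical"
  )
)

#' Metabolic-index result
#'
#' A per-site scalar summary \eqn{MI_i = \sum_j w_j z_{ij}} of the
#' standardized metabolite matrix, with the weight vector that produced it.
#'
#' @slot scheme one of \code{"mean"}, \code{"cov"}, \code{"pca"}.
#' @slot weights per-metabolite weights \eqn{w_j}.
#' @slot index per-site index values.
#' @slot loadings unit-norm PC1 loadings (pca scheme only, else length 0).
#' @slot explainedVar fraction of variance explained by PC1 (pca only, else
#'   \code{NA}).
#'
#' @seealso [miMean()], [miCov()], [miPCA()]
#' @exportClass MIResult
setClass("MIResult",
  representation(
    scheme = "character", weights = "numeric", index = "numeric",
    loadings = "numeric", explainedVar = "numeric"
  )
)

#' Global Moran's I result
#'
#' @slot I the statistic.
#' @slot expected the null expectation \eqn{-1/(n-1)}.
#' @slot pPerm two-sided permutation p-value, \eqn{(x+1)/(m+1)} estimator.
#' @slot nPerm number of permutations.
#'
#' @seealso [moransI()]
#' @exportClass MoranResult
setClass("MoranResult",
  representation(I = "numeric", expected = "numeric",
                 pPerm = "numeric", nPerm = "integer")
)

setValidity("MoranResult", function(object) {
  if (object@pPerm <= 0 || object@pPerm > 1) "pPerm must be in (0, 1]" else TRUE
})

#' Local Moran (LISA) result
#'
#' Per-site decomposition of Moran's I with HH/LL/HL/LH cluster quadrants
#' from the signs of the standardized value and its spatial lag, and
#' conditional-permutation p-values.
#'
#' @slot Ii per-site local statistics.
#' @slot quadrant factor with levels HH, LL, HL, LH.
#' @slot pPerm per-site conditional permutation p-values.
#' @slot nPerm number of permutations.
#'
#' @seealso [localMoran()]
#' @exportClass LisaResult
setClass("LisaResult",
  representation(Ii = "numeric", quadrant = "character",
                 pPerm = "numeric", nPerm = "integer")
)

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "FieldSpec", function(object) {
  cat(sprintf(
    "FieldSpec: %d sites on %g x %g m, ell=%g m, sill=%g, nugget=%g, mean=%g\n",
    object@nSites, object@extentM[1], object@extentM[2], object@corrLengthM,
    object@sill, object@nugget, object@mean))
  cat(sprintf("  origin (%g, %g) deg, GPS sigma %g m, seed %d\n",
              object@originDeg[1], object@originDeg[2], object@gpsSigmaM,
              object@seed))
})

setMethod("show", "FID", function(object) {
  cat(sprintf("FID: %d complex points, sw %.2f Hz at %.2f MHz\n",
              length(object@signal), object@acq@sweepWidthHz,
              object@acq@spectrometerFreqMHz))
})

setMethod("show", "NMRSpectrum", function(object) {
  cat(sprintf("NMRSpectrum: %d points, %.3f .. %.3f ppm%s\n",
              length(object@ppm), max(object@ppm), min(object@ppm),
              if (object@calibrated)
                sprintf(" (calibrated, ref %.3f ppm)", object@referencePpm)
              else " (uncalibrated)"))
})

setMethod("show", "SignalCatalog", function(object) {
  cat(sprintf("SignalCatalog: %d entries (%s)\n", nrow(object@entries),
              paste(head(object@entries$compound, 5), collapse = ", ")))
})

setMethod("show", "GeoDataset", function(object) {
  cat(sprintf("GeoDataset: %d sites x %d variables\n",
              nrow(object@sites), ncol(object@values)))
  if (ncol(object@values))
    cat("  variables:", paste(head(colnames(object@values), 8),
                              collapse = ", "),
        if (ncol(object@values) > 8) "..." else "", "\n")
})

setMethod("show", "SpatialWeights", function(object) {
  cat(sprintf(
    "SpatialWeights: %d sites, %s kernel, k=%d, %d nonzero weights%s\n",
    object@n, object@kernel, object@k, length(object@w),
    if (object@rowStandardized) ", row-standardized" else ""))
})

setMethod("show", "VariogramModel", function(object) {
  cat(sprintf(
    "VariogramModel (exponential): nugget=%.4g sill=%.4g length=%.4g m (effective range %.4g m)\n",
    object@nugget, object@sill, object@length, 3 * object@length))
  cat(sprintf("  %d nonempty bins%s\n", length(object@binCenters),
              if (object@flat) "; FLAT: no spatial structure detected" else ""))
})

setMethod("show", "MIResult", function(object) {
  cat(sprintf("MIResult (%s): %d sites, %d metabolites\n",
              object@scheme, length(object@index), length(object@weights)))
  if (object@scheme == "pca")
    cat(sprintf("  PC1 explains %.1f%% of variance\n",
                100 * object@explainedVar))
})

setMethod("show", "MoranResult", function(object) {
  cat(sprintf("Moran's I = %.4f (E[I] = %.4f), permutation p = %.4g (%d perms)\n",
              object@I, object@expected, object@pPerm, object@nPerm))
})

setMethod("show", "LisaResult", function(object) {
  tab <- table(factor(object@quadrant, levels = c("HH", "LL", "HL", "LH")))
  cat(sprintf("LISA: %d sites; quadrants HH=%d LL=%d HL=%d LH=%d; %d with p<=0.05\n",
              length(object@Ii), tab["HH"], tab["LL"], tab["HL"], tab["LH"],
              sum(object@pPerm <= 0.05)))
})
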