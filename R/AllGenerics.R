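#' Accessors for geometab classes
#'
#' Small accessor generics so downstream code never touches slots directly:
#' \code{ppm()} and \code{intensity()} for spectra (\code{intensity()} is the
#' real, absorption-mode part), \code{entries()} for signal catalogs,
#' \code{siteTable()}/\code{siteCoords()}/\code{concMatrix()} for
#' georeferenced datasets, \code{weightsMatrix()} for spatial weights (a
#' dense n-by-n matrix with zero diagonal), and \code{miIndex()}/
#' \code{miWeights()} for metabolic-index results.
#'
#' @param x the object.
#' @return The corresponding component; see each method.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("ppm", function(x) standardGeneric("ppm"))

#' @rdname accessors
#' @export
setGeneric("intensity", function(x) standardGeneric("intensity"))

#' @rdname accessors
#' @export
setGeneric("entries", function(x) standardGeneric("entries"))

#' @rdname accessors
#' @export
setGeneric("siteTable", function(x) standardGeneric("siteTable"))

#' @rdname accessors
#' @export
setGeneric("siteCoords", function(x) standardGeneric("siteCoords"))

#' @rdname accessors
#' @export
setGeneric("concMatrix", function(x) standardGeneric("concMatrix"))

#' @rdname accessors
#' @export
setGeneric("weightsMatrix", function(x) standardGeneric("weightsMatrix"))

#' @rdname accessors
#' @export
setGeneric("miIndex", function(x) standardGeneric("miIndex"))

#' @rdname accessors
#' @export
setGeneric("miWeights", function(x) standardGeneric("miWeights"))

#' @rdname accessors
#' @export
setMethod("ppm", "NMRSpectrum", function(x) x@ppm)

#' @rdname accessors
#' @export
setMethod("intensity", "NMRSpectrum", function(x) Re(x@signal))

#' @rdname accessors
#' @export
setMethod("entries", "SignalCatalog", function(x) x@entries)

#' @rdname accessors
#' @export
setMethod("siteTable", "GeoDataset", function(x) x@sites)

#' @rdname accessors
#' @export
setMethod("siteCoords", "GeoDataset", function(x)
  as.matrix(x@sites[, c("easting", "northing")]))

#' @rdname accessors
#' @export
setMethod("concMatrix", "GeoDataset", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("weightsMatrix", "SpatialWeights", function(x) {
  W <- matrix(0, x@n, x@n)
  W[cbind(x@i, x@j)] <- x@w
  W
})

#' @rdname accessors
#' @export
setMethod("miIndex", "MIResult", function(x) x@index)

#' @rdname accessors
#' @export
setMethod("miWeights", "MIResult", function(x) x@weights)
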