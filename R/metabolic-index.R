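#' Standard-scaled site-by-metabolite matrix
#'
#' Holds the standardized matrix \eqn{z_{ij} = (x_{ij} - \mu_j)/\sigma_j}
#' together with the per-metabolite means and standard deviations that
#' produced it.  The population convention (divide by n) is used for
#' \eqn{\sigma_j}, matching the standard-scaler convention, so standardized
#' columns have population variance exactly 1.
#'
#' @slot values the standardized matrix.
#' @slot mu,sigma per-metabolite raw mean and population sd.
#' @slot dropped names of zero-variance columns that were excluded.
#'
#' @seealso [standardScale()]
#' @exportClass ScaledMatrix
setClass("ScaledMatrix",
  representation(values = "matrix", mu = "numeric", sigma = "numeric",
                 dropped = "character"))

setMethod("show", "ScaledMatrix", function(object) {
  cat(sprintf("ScaledMatrix: %d sites x %d metabolites%s\n",
              nrow(object@values), ncol(object@values),
              if (length(object@dropped))
                paste0(" (dropped: ",
                       paste(object@dropped, collapse = ", "), ")")
              else ""))
})

.popSd <- function(x) sqrt(mean((x - mean(x))^2))

#' Standard scaling of a concentration matrix
#'
#' Centers and scales every column to mean 0 and population sd 1.
#' Zero-variance columns cannot be standardized; they are excluded with a
#' warning and recorded in the \code{dropped} slot.
#'
#' @param m numeric matrix, sites in rows, metabolites in columns.
#' @return A [ScaledMatrix-class].
#' @export
standardScale <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2L) stop("need at least 2 sites")
  if (is.null(colnames(m))) colnames(m) <- sprintf("V%d", seq_len(ncol(m)))
  mu <- colMeans(m)
  sigma <- apply(m, 2, .popSd)
  zero <- sigma == 0
  if (any(zero)) {
    warning("excluding zero-variance column(s): ",
            paste(colnames(m)[zero], collapse = ", "))
  }
  keep <- !zero
  z <- sweep(sweep(m[, keep, drop = FALSE], 2, mu[keep]), 2, sigma[keep], "/")
  new("ScaledMatrix", values = z, mu = mu[keep], sigma = sigma[keep],
      dropped = colnames(m)[zero])
}

#' Mean-weighted metabolic index
#'
#' \eqn{MI_i = \frac{1}{N}\sum_j z_{ij}}: every standardized metabolite gets
#' the same relevance.
#'
#' @param scaled a [ScaledMatrix-class].
#' @return An [MIResult-class] with scheme \code{"mean"}.
#' @export
miMean <- function(scaled) {
  stopifnot(is(scaled, "ScaledMatrix"))
  z <- scaled@values
  w <- setNames(rep(1 / ncol(z), ncol(z)), colnames(z))
  new("MIResult", scheme = "mean", weights = w,
      index = as.numeric(z %*% w), loadings = numeric(0),
      explainedVar = NA_real_)
}

#' CoV-weighted metabolic index
#'
#' Weights proportional to the coefficient of variation
#' \eqn{\mathrm{CoV}_j = \sigma_j/\mu_j} of each metabolite on the raw
#' concentration scale (standardized columns have mean 0, where CoV is
#' undefined), normalized so \eqn{\sum_j w_j = 1}, then applied to the
#' standardized variables: metabolites with high relative variability get
#' more weight.  Metabolites with zero raw mean are excluded with a warning.
#'
#' @param raw the raw (unscaled) concentration matrix.
#' @return An [MIResult-class] with scheme \code{"cov"}.
#' @export
miCov <- function(raw) {
  raw <- as.matrix(raw)
  if (is.null(colnames(raw))) colnames(raw) <- sprintf("V%d", seq_len(ncol(raw)))
  mu <- colMeans(raw)
  zeroMu <- mu == 0
  if (any(zeroMu)) {
    warning("excluding metabolite(s) with zero mean: ",
            paste(colnames(raw)[zeroMu], collapse = ", "))
    raw <- raw[, !zeroMu, drop = FALSE]
    mu <- mu[!zeroMu]
  }
  sigma <- apply(raw, 2, .popSd)
  cov <- sigma / mu
  if (all(cov == 0)) stop("all CoV are zero: CoV weights undefined")
  scaled <- standardScale(raw)
  keep <- colnames(scaled@values)
  w <- cov[keep] / sum(cov[keep])
  new("MIResult", scheme = "cov", weights = w,
      index = as.numeric(scaled@values %*% w), loadings = numeric(0),
      explainedVar = NA_real_)
}

#' First-principal-component metabolic index
#'
#' Loadings are the unit-norm eigenvector of the largest eigenvalue of the
#' (population) covariance matrix of the standardized data; the index is the
#' projection of the standardized rows on the loadings, so its population
#' variance equals the top eigenvalue.  The sign is fixed so that the
#' loading of largest absolute value is positive.
#'
#' @param scaled a [ScaledMatrix-class].
#' @return An [MIResult-class] with scheme \code{"pca"}: \code{weights} and
#'   \code{loadings} both hold the PC1 loadings, \code{explainedVar} the
#'   explained-variance fraction.
#' @export
miPCA <- function(scaled) {
  stopifnot(is(scaled, "ScaledMatrix"))
  z <- scaled@values
  if (nrow(z) < 2L || ncol(z) < 1L) stop("need >= 2 sites and >= 1 metabolite")
  C <- crossprod(z) / nrow(z)
  eig <- eigen(C, symmetric = TRUE)
  if (ncol(z) > 1L && eig$values[1] - eig$values[2] < 1e-9)
    warning("top eigenvalues are tied within 1e-9; PC1 direction is a deterministic but arbitrary choice within the tied subspace")
  v <- eig$vectors[, 1]
  if (v[which.max(abs(v))] < 0) v <- -v
  v <- setNames(v, colnames(z))
  new("MIResult", scheme = "pca", weights = v,
      index = as.numeric(z %*% v), loadings = v,
      explainedVar = eig$values[1] / sum(pmax(eig$values, 0)))
}
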