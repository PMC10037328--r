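#' Global Moran's I with a permutation test
#'
#' \deqn{I = \frac{n}{S_0}\,\frac{\sum_i\sum_j w_{ij} z_i z_j}{\sum_i z_i^2}}
#' with \eqn{z} the deviations from the mean and \eqn{S_0} the sum of all
#' weights; the null expectation is \eqn{-1/(n-1)}.  Significance is
#' assessed by random relabeling of the values over the sites: the two-sided
#' p-value counts permuted statistics at least as far from the expectation
#' as the observed one, with the \eqn{(x+1)/(m+1)} estimator.
#'
#' @param values numeric site values (finite, nonconstant).
#' @param weights a [SpatialWeights-class].
#' @param nPerm number of permutations (default 999; must be >= 99).
#' @param seed optional seed for the permutations.
#' @return A [MoranResult-class].
#' @export
moransI <- function(values, weights, nPerm = 999, seed = NULL) {
  stopifnot(is(weights, "SpatialWeights"))
  n <- weights@n
  if (length(values) != n) stop("length(values) must match the weights")
  if (!all(is.finite(values))) stop("values must be finite")
  if (.popSd(values) == 0) stop("Moran's I is undefined for constant values")
  if (nPerm < 99) stop("nPerm must be >= 99")
  S0 <- sum(weights@w)
  z <- values - mean(values)
  stat <- function(z) {
    (n / S0) * sum(weights@w * z[weights@i] * z[weights@j]) / sum(z^2)
  }
  I <- stat(z)
  e <- -1 / (n - 1)
  if (!is.null(seed)) set.seed(seed)
  Iperm <- vapply(seq_len(nPerm), function(b) stat(z[sample.int(n)]),
                  numeric(1))
  extreme <- sum(abs(Iperm - e) >= abs(I - e) - 1e-14)
  new("MoranResult", I = I, expected = e,
      pPerm = (extreme + 1) / (nPerm + 1), nPerm = as.integer(nPerm))
}

#' Local Moran (LISA) with conditional permutation
#'
#' \deqn{I_i = \frac{z_i}{m_2} \sum_j w_{ij} z_j,\qquad m_2 = \sum_i z_i^2/n,}
#' the per-site decomposition of global Moran's I.  Each site is assigned a
#' cluster quadrant from the signs of \eqn{z_i} and its spatial lag
#' \eqn{\sum_j w_{ij} z_j}: HH (high surrounded by high), LL, HL, LH.
#' P-values come from conditional permutation — site i's value is held
#' fixed while the remaining values are randomly reassigned to its
#' neighbours — two-sided on \eqn{I_i}, \eqn{(x+1)/(m+1)} estimator.
#'
#' @inheritParams moransI
#' @return A [LisaResult-class].
#' @export
localMoran <- function(values, weights, nPerm = 999, seed = NULL) {
  stopifnot(is(weights, "SpatialWeights"))
  n <- weights@n
  if (length(values) != n) stop("length(values) must match the weights")
  if (!all(is.finite(values))) stop("values must be finite")
  if (.popSd(values) == 0) stop("local Moran is undefined for constant values")
  z <- values - mean(values)
  m2 <- sum(z^2) / n
  lag <- numeric(n)
  agg <- tapply(weights@w * z[weights@j], weights@i, sum)
  lag[as.integer(names(agg))] <- agg
  Ii <- z / m2 * lag
  quadrant <- ifelse(z >= 0,
                     ifelse(lag >= 0, "HH", "HL"),
                     ifelse(lag >= 0, "LH", "LL"))
  if (!is.null(seed)) set.seed(seed)
  pPerm <- numeric(n)
  wByI <- split(seq_along(weights@i), weights@i)
  for (i in seq_len(n)) {
    idx <- wByI[[as.character(i)]]
    wi <- weights@w[idx]
    nNb <- length(wi)
    others <- z[-i]
    IiPerm <- vapply(seq_len(nPerm), function(b) {
      z[i] / m2 * sum(wi * others[sample.int(n - 1L, nNb)])
    }, numeric(1))
    extreme <- sum(abs(IiPerm) >= abs(Ii[i]) - 1e-14)
    pPerm[i] <- (extreme + 1) / (nPerm + 1)
  }
  new("LisaResult", Ii = Ii, quadrant = quadrant, pPerm = pPerm,
      nPerm = as.integer(nPerm))
}
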