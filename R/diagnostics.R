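#' Distribution diagnostics: histogram, KDE, Q-Q pairs
#'
#' The standard distribution summaries used to inspect per-metabolite (or
#' index) values before spatial analysis: a histogram with automatically
#' chosen bins (Sturges), a Gaussian kernel density estimate with
#' Silverman's rule-of-thumb bandwidth, and normal Q-Q pairs — sorted
#' values against standard-normal quantiles at plotting positions
#' \eqn{(i - 0.5)/n}.
#'
#' @param values numeric vector, n >= 3.
#' @return list with \code{histogram} (data.frame \code{mid}, \code{count}
#'   with bin edges as attribute \code{"breaks"}), \code{kde} (data.frame
#'   \code{x}, \code{density}), and \code{qq} (data.frame
#'   \code{theoretical}, \code{sample}).
#' @export
distributionDiagnostics <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 3L) stop("need at least 3 values")
  h <- graphics::hist(values, plot = FALSE)
  kd <- density(values, bw = "nrd0")
  ord <- sort(values)
  pp <- (seq_len(n) - 0.5) / n
  list(
    histogram = structure(data.frame(mid = h$mids, count = h$counts),
                          breaks = h$breaks),
    kde = data.frame(x = kd$x, density = kd$y),
    qq = data.frame(theoretical = qnorm(pp), sample = ord))
}

## number of local maxima of a KDE curve (used to count modes)
.kdeModes <- function(kde) {
  y <- kde$density
  sum(y[2:(length(y) - 1)] > y[1:(length(y) - 2)] &
        y[2:(length(y) - 1)] > y[3:length(y)] &
        y[2:(length(y) - 1)] > 0.05 * max(y))
}
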