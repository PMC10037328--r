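## WGS84 / UTM transverse Mercator, Krueger series in the third flattening n
## to order n^6 (sub-millimeter accuracy thousands of km from the central
## meridian).  Ellipsoid: a = 6378137 m, 1/f = 298.257223563; k0 = 0.9996,
## false easting 500000 m, false northing 10^7 m on the southern hemisphere.

.wgs84 <- local({
  a <- 6378137
  f <- 1 / 298.257223563
  n <- f / (2 - f)
  e <- sqrt(f * (2 - f))
  A <- a / (1 + n) * (1 + n^2 / 4 + n^4 / 64 + n^6 / 256)
  alpha <- c(
    n / 2 - 2 * n^2 / 3 + 5 * n^3 / 16 + 41 * n^4 / 180 - 127 * n^5 / 288 +
      7891 * n^6 / 37800,
    13 * n^2 / 48 - 3 * n^3 / 5 + 557 * n^4 / 1440 + 281 * n^5 / 630 -
      1983433 * n^6 / 1935360,
    61 * n^3 / 240 - 103 * n^4 / 140 + 15061 * n^5 / 26880 +
      167603 * n^6 / 181440,
    49561 * n^4 / 161280 - 179 * n^5 / 168 + 6601661 * n^6 / 7257600,
    34729 * n^5 / 80640 - 3418889 * n^6 / 1995840,
    212378941 * n^6 / 319334400)
  beta <- c(
    n / 2 - 2 * n^2 / 3 + 37 * n^3 / 96 - n^4 / 360 - 81 * n^5 / 512 +
      96199 * n^6 / 604800,
    n^2 / 48 + n^3 / 15 - 437 * n^4 / 1440 + 46 * n^5 / 105 -
      1118711 * n^6 / 3870720,
    17 * n^3 / 480 - 37 * n^4 / 840 - 209 * n^5 / 4480 + 5569 * n^6 / 90720,
    4397 * n^4 / 161280 - 11 * n^5 / 504 - 830251 * n^6 / 7257600,
    4583 * n^5 / 161280 - 108847 * n^6 / 3991680,
    20648693 * n^6 / 638668800)
  list(a = a, f = f, n = n, e = e, A = A, alpha = alpha, beta = beta,
       k0 = 0.9996, FE = 5e5, FN = 1e7)
})

.utmCentralMeridian <- function(zone) -183 + 6 * zone

#' Forward UTM projection (WGS84)
#'
#' Projects geographic WGS84 coordinates to Universal Transverse Mercator
#' easting/northing in meters (default zone 34N, EPSG:32634) with the
#' Krueger series in the third flattening to order \eqn{n^6}.
#'
#' @param lat,lon decimal degrees (vectorized); |lat| must be < 84.
#' @param zone UTM zone number (default 34, central meridian 21 E).
#' @param hemisphere \code{"N"} or \code{"S"}.
#' @return matrix with columns \code{easting}, \code{northing} (meters).
#' @examples
#' projectToUTM(40.82, 16.08)
#' @seealso [utmToWGS84()] for the inverse.
#' @export
projectToUTM <- function(lat, lon, zone = 34, hemisphere = c("N", "S")) {
  hemisphere <- match.arg(hemisphere)
  if (any(abs(lat) >= 84))
    stop("latitude out of range: UTM is defined for |lat| < 84 degrees")
  g <- .wgs84
  phi <- lat * pi / 180
  lam <- (lon - .utmCentralMeridian(zone)) * pi / 180
  chi <- .conformalLat(phi, g$e)
  xiP  <- atan2(tan(chi), cos(lam))
  etaP <- asinh(sin(lam) / sqrt(tan(chi)^2 + cos(lam)^2))
  xi <- xiP; eta <- etaP
  for (j in 1:6) {
    xi  <- xi  + g$alpha[j] * sin(2 * j * xiP) * cosh(2 * j * etaP)
    eta <- eta + g$alpha[j] * cos(2 * j * xiP) * sinh(2 * j * etaP)
  }
  E <- g$FE + g$k0 * g$A * eta
  N <- g$k0 * g$A * xi + if (hemisphere == "S") g$FN else 0
  cbind(easting = E, northing = N)
}

.conformalLat <- function(phi, e) {
  2 * atan(tan(pi / 4 + phi / 2) *
             ((1 - e * sin(phi)) / (1 + e * sin(phi)))^(e / 2)) - pi / 2
}

#' Inverse UTM projection (WGS84)
#'
#' Inverse of [projectToUTM()]; the round trip closes to well below a
#' micrometer.
#'
#' @param easting,northing meters (vectorized).
#' @param zone UTM zone number.
#' @param hemisphere \code{"N"} or \code{"S"}.
#' @return matrix with columns \code{lat}, \code{lon} in decimal degrees.
#' @export
utmToWGS84 <- function(easting, northing, zone = 34,
                       hemisphere = c("N", "S")) {
  hemisphere <- match.arg(hemisphere)
  g <- .wgs84
  xi  <- (northing - if (hemisphere == "S") g$FN else 0) / (g$k0 * g$A)
  eta <- (easting - g$FE) / (g$k0 * g$A)
  xiP <- xi; etaP <- eta
  for (j in 1:6) {
    xiP  <- xiP  - g$beta[j] * sin(2 * j * xi) * cosh(2 * j * eta)
    etaP <- etaP - g$beta[j] * cos(2 * j * xi) * sinh(2 * j * eta)
  }
  chi <- atan2(sin(xiP), sqrt(sinh(etaP)^2 + cos(xiP)^2))
  lam <- atan2(sinh(etaP), cos(xiP))
  phi <- chi
  for (it in 1:15) {
    phi <- 2 * atan(tan(pi / 4 + chi / 2) *
                      ((1 + g$e * sin(phi)) /
                         (1 - g$e * sin(phi)))^(g$e / 2)) - pi / 2
  }
  cbind(lat = phi * 180 / pi,
        lon = .utmCentralMeridian(zone) + lam * 180 / pi)
}

#' Assemble a georeferenced dataset
#'
#' Builds a [GeoDataset-class] from latitude/longitude positions and a
#' site-by-metabolite matrix, projecting the positions to UTM meters.
#'
#' @param lat,lon decimal degrees (WGS84), one per site.
#' @param values site-by-variable numeric matrix (may have 0 columns).
#' @param id optional site identifiers.
#' @param zone,hemisphere passed to [projectToUTM()].
#' @return A validated [GeoDataset-class].
#' @export
geoDataset <- function(lat, lon, values = NULL, id = NULL, zone = 34,
                       hemisphere = "N") {
  n <- length(lat)
  stopifnot(length(lon) == n)
  if (is.null(id)) id <- seq_len(n)
  if (is.null(values)) values <- matrix(numeric(0), n, 0)
  values <- as.matrix(values)
  en <- projectToUTM(lat, lon, zone = zone, hemisphere = hemisphere)
  new("GeoDataset",
      sites = data.frame(id = id, lat = lat, lon = lon,
                         easting = en[, "easting"],
                         northing = en[, "northing"]),
      values = values)
}
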