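# Shared fixtures: small catalogs, quick spectra and field layouts built in
# code so every test input is generated at run time.

quickAcq <- function(nPoints = 8192L)
  acquisitionParams(nPoints = as.integer(nPoints))

# single-compound catalog at an arbitrary shift
oneLineCatalog <- function(shift = 3.0, shape = "s", compound = "X")
  signalCatalog(data.frame(compound = compound, shift_ppm = shift,
                           shape = shape, stringsAsFactors = FALSE))

# noise-free processed spectrum from a catalog + amplitudes
quickSpectrum <- function(catalog, amplitudes, lbHz = 0.3, calibrate = TRUE,
                          acq = quickAcq(), ...) {
  fid <- synthesizeFID(catalog, amplitudes, acq = acq, ...)
  if (lbHz > 0) fid <- apodize(fid, lbHz)
  sp <- transformSpectrum(fid)
  if (calibrate) sp <- calibrateSpectrum(sp) else sp
}

# jittered-grid field positions projected to meters
quickField <- function(nSites = 60, extent = c(500, 200), ell = 30,
                       sill = 1, nugget = 0.1, seed = 1, gpsSigmaM = 3) {
  spec <- fieldSpec(nSites = nSites, extentM = extent, corrLengthM = ell,
                    sill = sill, nugget = nugget, gpsSigmaM = gpsSigmaM,
                    seed = seed)
  pos <- samplePositions(spec)
  xy <- projectToUTM(pos$lat, pos$lon)
  list(spec = spec, pos = pos, xy = xy)
}

# brute-force Moran's I: explicit double loop over the dense weight matrix
bruteMoran <- function(z, W) {
  n <- length(z)
  zc <- z - mean(z)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    num <- num + W[i, j] * zc[i] * zc[j]
  (n / sum(W)) * num / sum(zc^2)
}

bruteLocalMoran <- function(z, W) {
  n <- length(z)
  zc <- z - mean(z)
  m2 <- sum(zc^2) / n
  vapply(seq_len(n), function(i) zc[i] / m2 * sum(W[i, ] * zc), numeric(1))
}
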