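test_that("apodization with lb = 0 is the identity and FWHM tracks lb", {
  catal <- oneLineCatalog(shift = 4.7)
  ## long acquisition so the apodized FID decays fully (no truncation)
  fid <- synthesizeFID(catal, 1, acq = quickAcq(65536L), dssAmplitude = 0,
                       linewidthHz = 1e-6)   # effectively zero decay
  expect_identical(apodize(fid, 0)@signal, fid@signal)

  fitFwhm <- function(lb) {
    sp <- transformSpectrum(apodize(fid, lb))
    sp@calibrated <- TRUE
    q <- deconvolve(sp, oneLineCatalog(shift = 4.7), initFwhmHz = max(lb, 0.2))
    q$fitted_fwhm_hz
  }
  ## zero-decay line apodized with 0.3 Hz -> Lorentzian of FWHM 0.3 Hz
  expect_equal(fitFwhm(0.3), 0.3, tolerance = 0.02)
  ## monotone: larger lb -> larger fitted width
  expect_lt(fitFwhm(0.3), fitFwhm(1.0))
  expect_lt(fitFwhm(1.0), fitFwhm(3.0))
})

test_that("transform places a complex exponential at its ppm and conserves energy", {
  acq <- quickAcq(4096L)
  f0 <- 347.1   # Hz off carrier
  t <- (seq_len(4096L) - 1) / acq@sweepWidthHz
  sig <- exp(2i * pi * f0 * t) * exp(-pi * 1 * t)
  fid <- new("FID", signal = sig, acq = acq)
  sp <- transformSpectrum(fid, zeroFill = FALSE)
  pk <- which.max(intensity(sp))
  expect_equal(ppm(sp)[pk], acq@carrierPpm + f0 / acq@spectrometerFreqMHz,
               tolerance = acq@sweepWidthHz / 4096 / acq@spectrometerFreqMHz)
  ## Parseval with the conventional half-first-point: energy is conserved
  s2 <- sig; s2[1] <- s2[1] / 2
  expect_equal(sum(Mod(sp@signal)^2) / 4096, sum(Mod(s2)^2),
               tolerance = 1e-9)
  ## linearity
  fid2 <- new("FID", signal = rev(sig), acq = acq)
  both <- new("FID", signal = sig + rev(sig), acq = acq)
  expect_equal(transformSpectrum(both)@signal,
               transformSpectrum(fid)@signal + transformSpectrum(fid2)@signal,
               tolerance = 1e-12)
  expect_error(transformSpectrum(new("FID", signal = complex(0),
                                     acq = quickAcq(0L))))
})

test_that("phase correction: identity, periodicity, and auto recovery", {
  catal <- signalCatalog(data.frame(
    compound = c("A", "B", "C"), shift_ppm = c(1.5, 4.2, 7.9),
    shape = c("s", "s", "s"), stringsAsFactors = FALSE))
  sp <- quickSpectrum(catal, c(1, 2, 1.5), calibrate = FALSE,
                      dssAmplitude = 0)
  expect_equal(phaseCorrect(sp, 0, 0)@signal, sp@signal)
  expect_equal(phaseCorrect(sp, 360, 0)@signal, sp@signal, tolerance = 1e-12)
  ## dephase by a known (phi0, phi1), auto-phase back to absorption
  bad <- phaseCorrect(sp, -40, -110)
  ap <- autoPhase(bad)
  y <- intensity(ap$spectrum)
  negFrac <- sum(pmin(y, 0)^2) / sum(y^2)
  expect_lt(negFrac, 0.01)
  ## recovered absorption trace matches the known-phase reconstruction
  expect_equal(max(y), max(intensity(sp)), tolerance = 0.01)
})

test_that("baseline correction recovers a known smooth baseline", {
  catal <- signalCatalog(data.frame(
    compound = c("A", "B"), shift_ppm = c(2.2, 6.8), shape = c("s", "s"),
    stringsAsFactors = FALSE))
  sp <- quickSpectrum(catal, c(1, 0.6), calibrate = FALSE, dssAmplitude = 0)
  x <- ppm(sp); y <- intensity(sp)
  base <- 0.02 * max(y) * (x - 4)^2 / 10
  dirty <- new("NMRSpectrum", ppm = x,
               signal = sp@signal + complex(real = base),
               calibrated = FALSE, referencePpm = NA_real_, acq = sp@acq)
  cor <- baselineCorrect(dirty)
  est <- attr(cor, "baseline")
  expect_lt(max(abs(est - base)) / max(y), 0.02)
  ## peak-free regions end flat
  far <- abs(x - 2.2) > 0.3 & abs(x - 6.8) > 0.3
  expect_lt(mean(abs(intensity(cor)[far])), 0.005 * max(y))
  ## integral of an isolated line preserved within 1%
  win <- abs(x - 6.8) < 0.3
  step <- abs(median(diff(x)))
  expect_equal(sum(intensity(cor)[win]) * step, sum(y[win]) * step,
               tolerance = 0.01)
  ## near-identity on a baseline-free spectrum; flat zero returns unchanged
  cor0 <- baselineCorrect(sp)
  expect_lt(max(abs(intensity(cor0) - y)) / max(y), 0.005)
  zero <- new("NMRSpectrum", ppm = x, signal = complex(real = numeric(length(x))),
              calibrated = FALSE, referencePpm = NA_real_, acq = sp@acq)
  expect_identical(baselineCorrect(zero), zero)
})

test_that("DSS calibration shifts the axis rigidly onto the reference", {
  catal <- signalCatalog(data.frame(
    compound = c("A", "B"), shift_ppm = c(3.1, 7.4), shape = c("s", "s"),
    stringsAsFactors = FALSE))
  sp <- quickSpectrum(catal, c(1, 1), calibrate = FALSE, dssPpm = 0.080)
  cal <- calibrateSpectrum(sp)
  shift <- attr(cal, "shift")
  expect_equal(shift, 0.015 - 0.080, tolerance = 2e-4)
  ## rigidity: every axis point moves by exactly the same offset
  expect_equal(ppm(cal), ppm(sp) + shift)
  ## other line positions move with the axis
  pkB <- ppm(cal)[which.min(abs(ppm(cal) - (7.4 + shift)))]
  expect_equal(pkB, 7.4 + shift, tolerance = 1e-3)
  ## already-calibrated spectrum: residual shift below one axis step
  cal2 <- calibrateSpectrum(cal)
  expect_lt(abs(attr(cal2, "shift")), abs(median(diff(ppm(cal)))))
  ## no peak in the window -> calibration failure naming the window
  far <- quickSpectrum(catal, c(1, 1), calibrate = FALSE, dssAmplitude = 0)
  expect_error(calibrateSpectrum(far), "window \\[-0.5, 0.5\\]")
})

test_that("the full processing chain preserves relative line areas within 1%", {
  catal <- signalCatalog(data.frame(
    compound = c("A", "B", "C"), shift_ppm = c(1.2, 4.0, 7.7),
    shape = c("s", "d", "s"), stringsAsFactors = FALSE))
  amps <- c(1.0, 2.5, 0.5)
  fid <- apodize(synthesizeFID(catal, amps, acq = quickAcq()), 0.3)
  sp <- transformSpectrum(fid)
  sp <- phaseCorrect(sp, 0, 0)
  sp <- baselineCorrect(sp)
  sp <- calibrateSpectrum(sp)
  q <- deconvolve(sp, catal)
  ratios <- q$area / amps
  expect_lt(max(ratios) / min(ratios) - 1, 0.01)
})

test_that("processing is pure: identical inputs give identical outputs", {
  catal <- oneLineCatalog()
  fid <- synthesizeFID(catal, 1, acq = quickAcq(1024L))
  s1 <- transformSpectrum(apodize(fid, 0.3))
  s2 <- transformSpectrum(apodize(fid, 0.3))
  expect_identical(s1@signal, s2@signal)
  expect_identical(ppm(s1), ppm(s2))
})
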