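#' Construct acquisition parameters
#'
#' Defaults mirror a 600 MHz proton experiment: 600.13 MHz Larmor frequency,
#' a 12 ppm sweep centered at 4.7 ppm, 16384 complex points.
#'
#' @param spectrometerFreqMHz proton frequency in MHz.
#' @param sweepWidthHz spectral width in Hz.
#' @param nPoints number of complex time-domain points.
#' @param carrierPpm transmitter offset (axis center) in ppm.
#' @return An [AcquisitionParams-class].
#' @export
acquisitionParams <- function(spectrometerFreqMHz = 600.13,
                              sweepWidthHz = 12 * spectrometerFreqMHz,
                              nPoints = 16384L, carrierPpm = 4.7) {
  if (sweepWidthHz <= 0)
    stop("inconsistent acquisition parameters: dwell time <= 0")
  new("AcquisitionParams",
      spectrometerFreqMHz = as.numeric(spectrometerFreqMHz),
      sweepWidthHz = as.numeric(sweepWidthHz),
      nPoints = as.integer(nPoints), carrierPpm = as.numeric(carrierPpm))
}

## One multiplet = sum of Lorentzian component lines.  Offsets in Hz from the
## multiplet center, relative intensities normalized to sum 1 so the summed
## component areas equal the multiplet area.
.multipletComponents <- function(shape, jHz) {
  switch(shape,
    s = list(offsetHz = 0, relInt = 1),
    d = list(offsetHz = c(-jHz[1] / 2, jHz[1] / 2), relInt = c(1, 1) / 2),
    dd = {
      a <- jHz[1] / 2; b <- jHz[2] / 2
      list(offsetHz = c(-a - b, -a + b, a - b, a + b),
           relInt = rep(1 / 4, 4))
    },
    `5m` = list(offsetHz = jHz[1] * (-2:2),
                relInt = c(1, 4, 6, 4, 1) / 16),
    stop("unknown multiplet shape: ", shape))
}

#' Synthesize a free induction decay from a signal catalog
#'
#' Builds the complex time-domain signal as a sum of decaying complex
#' exponentials, one per multiplet component line: frequency from the
#' catalogued chemical shift (plus the J-coupling splitting pattern), decay
#' rate \eqn{\pi w} from the target linewidth \eqn{w} (Hz).  A DSS reference
#' singlet is always included; its true position can be offset from the
#' nominal 0.015 ppm to exercise axis calibration downstream.  Amplitudes
#' are calibrated so that, after [transformSpectrum()], the integral of each
#' multiplet over ppm equals its amplitude.
#'
#' @param catalog a [SignalCatalog-class].
#' @param amplitudes nonnegative numeric, one per catalog entry.
#' @param acq an [AcquisitionParams-class].
#' @param linewidthHz intrinsic linewidth of every line before apodization
#'   (default 0.8 Hz, a typical well-shimmed 1H linewidth).
#' @param noiseSd standard deviation of the complex Gaussian noise added to
#'   each time-domain sample (0 = noise free).
#' @param dssAmplitude amplitude of the DSS reference line.
#' @param dssPpm true position at which the DSS line is synthesized
#'   (default the nominal 0.015 ppm; offset it to test calibration).
#' @param seed seed for the noise draw.
#' @return A [FID-class].
#' @export
synthesizeFID <- function(catalog, amplitudes, acq = acquisitionParams(),
                          linewidthHz = 0.8, noiseSd = 0,
                          dssAmplitude = 1, dssPpm = 0.015, seed = NULL) {
  stopifnot(is(catalog, "SignalCatalog"), is(acq, "AcquisitionParams"))
  validObject(acq)
  e <- entries(catalog)
  if (length(amplitudes) != nrow(e))
    stop("need one amplitude per catalog entry")
  if (any(amplitudes < 0)) stop("amplitudes must be >= 0")
  shifts <- c(e$shift_ppm, dssPpm)
  shapes <- c(e$shape, "s")
  js     <- c(e$j_hz, list(numeric(0)))
  amps   <- c(amplitudes, dssAmplitude)

  n  <- acq@nPoints
  dt <- 1 / acq@sweepWidthHz
  t  <- (seq_len(n) - 1) * dt
  sig <- complex(real = numeric(n), imaginary = numeric(n))
  for (k in seq_along(shifts)) {
    if (amps[k] == 0) next
    comp <- .multipletComponents(shapes[k], js[[k]])
    f0 <- (shifts[k] - acq@carrierPpm) * acq@spectrometerFreqMHz
    for (c in seq_along(comp$offsetHz)) {
      f <- f0 + comp$offsetHz[c]
      sig <- sig + amps[k] * comp$relInt[c] *
        exp((2i * pi * f - pi * linewidthHz) * t)
    }
  }
  ## unit amplitude -> unit integral over the ppm axis after FFT
  sig <- sig * 2 * dt * acq@spectrometerFreqMHz
  if (noiseSd > 0) {
    if (!is.null(seed)) set.seed(seed)
    sig <- sig + complex(real = rnorm(n, 0, noiseSd),
                         imaginary = rnorm(n, 0, noiseSd))
  }
  new("FID", signal = sig, acq = acq)
}
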