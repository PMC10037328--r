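#' Read / write spectra in the two-column text format
#'
#' A spectrum is stored as plain text with two whitespace-separated columns
#' (ppm, intensity) — the real, absorption-mode trace — plus a YAML sidecar
#' header \code{<path>.yml} carrying the acquisition parameters and the
#' calibration state.  The format is portable and diffable; the imaginary
#' part is not persisted, so write spectra only after phasing.
#'
#' @param spec an [NMRSpectrum-class].
#' @param path file path for the two-column table (sidecar written next to
#'   it as \code{<path>.yml}).
#' @return \code{writeSpectrum} returns \code{path} invisibly;
#'   \code{readSpectrum} returns an [NMRSpectrum-class] with a purely real
#'   signal.
#' @export
writeSpectrum <- function(spec, path) {
  stopifnot(is(spec, "NMRSpectrum"))
  df <- data.frame(ppm = spec@ppm, intensity = Re(spec@signal))
  utils::write.table(df, path, row.names = FALSE, col.names = TRUE,
                     quote = FALSE, sep = "\t")
  meta <- list(
    spectrometer_freq_mhz = spec@acq@spectrometerFreqMHz,
    sweep_width_hz        = spec@acq@sweepWidthHz,
    n_points              = spec@acq@nPoints,
    carrier_ppm           = spec@acq@carrierPpm,
    calibrated            = spec@calibrated,
    reference_shift_ppm   = if (is.na(spec@referencePpm)) NULL
                            else spec@referencePpm)
  yaml::write_yaml(meta, paste0(path, ".yml"))
  invisible(path)
}

#' @rdname writeSpectrum
#' @export
readSpectrum <- function(path) {
  df <- utils::read.table(path, header = TRUE)
  meta <- yaml::read_yaml(paste0(path, ".yml"))
  acq <- acquisitionParams(
    spectrometerFreqMHz = meta$spectrometer_freq_mhz,
    sweepWidthHz = meta$sweep_width_hz,
    nPoints = as.integer(meta$n_points),
    carrierPpm = meta$carrier_ppm)
  ord <- order(df$ppm, decreasing = TRUE)
  new("NMRSpectrum", ppm = df$ppm[ord],
      signal = complex(real = df$intensity[ord],
                       imaginary = numeric(nrow(df))),
      calibrated = isTRUE(meta$calibrated),
      referencePpm = if (is.null(meta$reference_shift_ppm)) NA_real_
                     else meta$reference_shift_ppm,
      acq = acq)
}
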