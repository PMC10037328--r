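## Built-in quantification catalogs: compound, multiplet-center chemical
## shift (ppm) and line-shape code for the durum-wheat extracts.  Shape codes:
## s singlet, d doublet, dd doublet of doublets, 5m 1:4:6:4:1 quintet.

.catalogShoots <- function() data.frame(
  compound = c("Val", "Ile", "U1", "U2", "Thr", "Ala", "GABA", "acetic acid",
               "Asn", "U5", "U6", "U7", "b-glucose", "a-glucose", "PS1",
               "PS2", "PS3", "PS4", "sucrose", "PS5", "formate"),
  shift_ppm = c(0.9958, 1.0139, 1.1119, 1.2528, 1.3356, 1.4850, 1.9073,
                1.9230, 2.8734, 3.2063, 3.2694, 3.4551, 4.6511, 5.2388,
                5.3860, 5.3944, 5.4064, 5.4100, 5.4181, 5.4378, 8.4586),
  shape = c("d", "d", "s", "s", "d", "d", "5m", "s", "dd", "s", "s", "s",
            "d", "d", "d", "d", "d", "d", "d", "d", "s"),
  stringsAsFactors = FALSE)

.catalogSpikes <- function() data.frame(
  compound = c("Val", "Ile", "U1", "U2", "Thr", "Ala", "GABA", "acetic acid",
               "succinate", "malate", "Asn", "U5", "U6", "b-glucose",
               "a-glucose", "PS1", "PS4", "sucrose", "PS6", "formate"),
  shift_ppm = c(0.9946, 1.0132, 1.1100, 1.2515, 1.3335, 1.4828, 1.9073,
                1.9202, 2.4090, 2.6770, 2.8682, 3.2052, 3.2683, 4.6613,
                5.2373, 5.3840, 5.4094, 5.4168, 5.4367, 8.4584),
  shape = c("d", "d", "s", "s", "d", "d", "5m", "s", "s", "dd", "dd", "s",
            "s", "d", "d", "d", "d", "d", "d", "s"),
  stringsAsFactors = FALSE)

#' Build or fetch a signal catalog
#'
#' Constructs a [SignalCatalog-class] either from one of the two built-in
#' durum-wheat catalogs (\code{"shoots"}: 21 signals quantified in wheat-shoot
#' extracts; \code{"spikes"}: 20 signals of blooming-spike extracts) or from
#' a data.frame with columns \code{compound}, \code{shift_ppm}, \code{shape}
#' and optionally \code{j_hz} (a list column, or a character column with
#' couplings separated by \code{";"}).
#'
#' Couplings missing from the input are filled with package defaults: 7 Hz
#' for \code{d} and \code{5m}, (7, 3) Hz for \code{dd} — typical vicinal /
#' geminal 1H couplings; they serve as fit starting values and may be refined
#' during deconvolution.
#'
#' @param x \code{"shoots"}, \code{"spikes"}, or a data.frame.
#' @return A [SignalCatalog-class].
#' @examples
#' signalCatalog("shoots")
#' @export
signalCatalog <- function(x = c("shoots", "spikes")) {
  if (is.character(x) && length(x) == 1L) {
    x <- match.arg(x)
    df <- if (x == "shoots") .catalogShoots() else .catalogSpikes()
  } else if (is.data.frame(x)) {
    df <- as.data.frame(x, stringsAsFactors = FALSE)
  } else stop("x must be 'shoots', 'spikes', or a data.frame")
  df <- df[order(df$shift_ppm), , drop = FALSE]
  rownames(df) <- NULL
  if (!all(df$shape %in% c("s", "d", "dd", "5m")))
    stop("shape codes restricted to s, d, dd, 5m")
  if (is.null(df$j_hz)) {
    df$j_hz <- vector("list", nrow(df))
  } else if (is.character(df$j_hz)) {
    df$j_hz <- lapply(df$j_hz, function(s)
      if (is.na(s) || !nzchar(s)) NULL
      else as.numeric(strsplit(s, ";", fixed = TRUE)[[1]]))
  } else if (is.numeric(df$j_hz)) {
    df$j_hz <- lapply(df$j_hz, function(v) if (is.na(v)) NULL else v)
  }
  df$j_hz <- mapply(function(j, shape) {
    if (!length(j) || all(is.na(j))) j <- .defaultJ(shape)
    nc <- switch(shape, s = 0L, d = 1L, dd = 2L, `5m` = 1L)
    if (length(j) < nc) j <- c(j, .defaultJ(shape))[seq_len(nc)]
    j[seq_len(nc)]
  }, df$j_hz, df$shape, SIMPLIFY = FALSE)
  new("SignalCatalog", entries = df)
}

.defaultJ <- function(shape)
  switch(shape, s = numeric(0), d = 7, dd = c(7, 3), `5m` = 7)

#' Read / write a signal catalog as CSV
#'
#' Columns \code{compound}, \code{shift_ppm}, \code{shape}, \code{j_hz}
#' (couplings joined with \code{";"}).
#'
#' @param path file path.
#' @param catalog a [SignalCatalog-class].
#' @return \code{readCatalogCSV} returns a [SignalCatalog-class];
#'   \code{writeCatalogCSV} returns \code{path} invisibly.
#' @export
readCatalogCSV <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  signalCatalog(df)
}

#' @rdname readCatalogCSV
#' @export
writeCatalogCSV <- function(catalog, path) {
  stopifnot(is(catalog, "SignalCatalog"))
  df <- entries(catalog)
  df$j_hz <- vapply(df$j_hz, function(j) paste(j, collapse = ";"), "")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
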