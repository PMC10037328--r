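#' Run the full spatial-metabolomics pipeline
#'
#' Orchestrates the stages end-to-end from a single declarative config:
#' quantification of per-sample spectra against a signal catalog (or direct
#' loading of an already-quantified georeferenced table), standard scaling,
#' the chosen metabolic index, and per-variable spatial analysis (empirical
#' variogram, exponential model fit, ordinary kriging — falling back to
#' thin-plate RBF interpolation when the variogram is flat — global Moran
#' and LISA).  All tables and surfaces are written under
#' \code{output_dir}, together with a JSON run manifest recording the
#' package version, seed, parameters, per-stage status and output paths; a
#' failed stage is recorded in the manifest and partial outputs are kept.
#'
#' @param config a named list or the path of a YAML file with fields:
#'   \code{geodataset_path} (CSV or GeoJSON of positions + concentrations)
#'   \emph{or} \code{spectra_dir} + \code{catalog_path} +
#'   \code{positions_path} (CSV with \code{lat}, \code{lon} in the
#'   alphabetical order of the spectrum files); \code{mi_scheme}
#'   (\code{"pca"}, \code{"mean"} or \code{"cov"}; default pca);
#'   \code{k_neighbors} (default 7); \code{n_bins} (default 20);
#'   \code{n_perm} (default 999); \code{grid_size} (default 100);
#'   \code{seed} (default 1); \code{output_dir}.
#' @return The manifest, invisibly (also written as
#'   \code{manifest.json}).
#' @export
runPipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$output_dir))
  cfg <- utils::modifyList(
    list(mi_scheme = "pca", k_neighbors = 7L, n_bins = 20L, n_perm = 999L,
         grid_size = 100L, seed = 1L, tolerance_ppm = 0.01), config)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package = "geometab",
    version = as.character(utils::packageVersion("geometab")),
    r_version = R.version.string,
    config = cfg, stages = list(), outputs = list())
  .finish <- function() {
    jsonlite::write_json(manifest, file.path(cfg$output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(manifest)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(list(ok = TRUE, value = expr),
                    error = function(e) list(ok = FALSE,
                                             error = conditionMessage(e)))
    manifest$stages[[name]] <<- list(
      status = if (out$ok) "ok" else "error",
      seconds = round(proc.time()[["elapsed"]] - t0, 3),
      error = if (out$ok) NULL else out$error)
    out
  }

  ## ---- stage 1: concentrations + positions -------------------------------
  s1 <- stage("quantify", {
    if (!is.null(cfg$geodataset_path)) {
      gd <- if (grepl("\\.(geo)?json$", cfg$geodataset_path,
                      ignore.case = TRUE))
        readGeoJSON(cfg$geodataset_path)
      else readGeoCSV(cfg$geodataset_path)
      gd
    } else {
      catalog <- readCatalogCSV(cfg$catalog_path)
      files <- sort(list.files(cfg$spectra_dir, pattern = "\\.tsv$",
                               full.names = TRUE))
      if (!length(files)) stop("no .tsv spectra in ", cfg$spectra_dir)
      spectra <- lapply(files, readSpectrum)
      names(spectra) <- sub("\\.tsv$", "", basename(files))
      q <- quantifyDataset(spectra, catalog,
                           tolerancePpm = cfg$tolerance_ppm)
      pos <- read.csv(cfg$positions_path)
      keep <- !(names(spectra) %in% q$flagged)
      gd <- geoDataset(pos$lat[keep], pos$lon[keep], q$matrix,
                       id = names(spectra)[keep])
      attr(gd, "flagged") <- q$flagged
      gd
    }
  })
  if (!s1$ok) return(.finish())
  gd <- s1$value
  concPath <- file.path(cfg$output_dir, "concentrations.csv")
  writeGeoCSV(gd, concPath)
  manifest$outputs$concentrations <- concPath
  if (length(attr(gd, "flagged")))
    manifest$outputs$flagged_samples <- attr(gd, "flagged")

  ## ---- stage 2: scaling + metabolic index --------------------------------
  s2 <- stage("metabolic_index", {
    scaled <- standardScale(concMatrix(gd))
    mi <- switch(cfg$mi_scheme,
                 mean = miMean(scaled),
                 cov  = miCov(concMatrix(gd)),
                 pca  = miPCA(scaled),
                 stop("unknown mi_scheme: ", cfg$mi_scheme))
    list(scaled = scaled, mi = mi)
  })
  if (!s2$ok) return(.finish())
  scaled <- s2$value$scaled; mi <- s2$value$mi
  miPath <- file.path(cfg$output_dir, "metabolic_index.csv")
  write.csv(cbind(siteTable(gd)[c("id", "lat", "lon", "easting", "northing")],
                  MI = miIndex(mi)), miPath, row.names = FALSE)
  wPath <- file.path(cfg$output_dir, "mi_weights.csv")
  wdf <- data.frame(metabolite = names(miWeights(mi)),
                    weight = as.numeric(miWeights(mi)))
  if (mi@scheme == "pca") {
    wdf$loading <- as.numeric(mi@loadings)
    manifest$outputs$explained_var_fraction <- mi@explainedVar
  }
  write.csv(wdf, wPath, row.names = FALSE)
  manifest$outputs$metabolic_index <- miPath
  manifest$outputs$mi_weights <- wPath

  ## ---- stage 3: spatial analysis per variable + MI -----------------------
  s3 <- stage("spatial", {
    xy <- siteCoords(gd)
    W <- kernelWeights(xy, k = cfg$k_neighbors)
    grid <- makeGrid(xy, nx = cfg$grid_size, ny = cfg$grid_size)
    vars <- cbind(scaled@values, MI = miIndex(mi))
    surf <- list(); morans <- list(); lisas <- list()
    for (v in seq_len(ncol(vars))) {
      nm <- colnames(vars)[v]
      z <- vars[, v]
      emp <- empiricalVariogram(xy, z, nBins = cfg$n_bins)
      vm <- tryCatch(suppressWarnings(fitExponentialVariogram(emp)),
                     error = function(e) NULL)
      useRbf <- is.null(vm) || vm@flat
      sv <- if (useRbf) rbfInterpolate(xy, z, grid)
            else ordinaryKrige(xy, z, vm, grid)
      fn <- file.path(cfg$output_dir,
                      sprintf("surface_%s.csv", gsub("[^A-Za-z0-9]", "_", nm)))
      write.csv(sv[c("easting", "northing", "prediction")], fn,
                row.names = FALSE)
      surf[[nm]] <- list(
        path = fn, method = if (useRbf) "rbf" else "kriging",
        variogram = if (is.null(vm)) NULL else
          list(nugget = vm@nugget, sill = vm@sill, length = vm@length,
               effective_range = 3 * vm@length, flat = vm@flat))
      mres <- moransI(z, W, nPerm = cfg$n_perm, seed = cfg$seed + v)
      morans[[nm]] <- data.frame(variable = nm, I = mres@I,
                                 expected = mres@expected,
                                 p_perm = mres@pPerm, n_perm = mres@nPerm)
      lres <- localMoran(z, W, nPerm = cfg$n_perm, seed = cfg$seed + v)
      lisas[[nm]] <- data.frame(variable = nm, id = siteTable(gd)$id,
                                Ii = lres@Ii, quadrant = lres@quadrant,
                                p_perm = lres@pPerm)
    }
    list(surfaces = surf,
         moran = do.call(rbind, morans), lisa = do.call(rbind, lisas))
  })
  if (s3$ok) {
    moranPath <- file.path(cfg$output_dir, "moran.csv")
    write.csv(s3$value$moran, moranPath, row.names = FALSE)
    lisaPath <- file.path(cfg$output_dir, "lisa.csv")
    write.csv(s3$value$lisa, lisaPath, row.names = FALSE)
    manifest$outputs$moran <- moranPath
    manifest$outputs$lisa <- lisaPath
    manifest$outputs$surfaces <- s3$value$surfaces
  }
  .finish()
}
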