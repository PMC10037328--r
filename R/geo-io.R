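#' Read / write a georeferenced dataset as GeoJSON or CSV
#'
#' GeoJSON: a FeatureCollection of Point features in WGS84 (coordinates
#' \code{[lon, lat]}), properties holding the site id and the per-metabolite
#' concentrations.  CSV: columns \code{lat}, \code{lon} followed by one
#' column per metabolite.  Projected coordinates are recomputed on read via
#' [projectToUTM()].
#'
#' @param gd a [GeoDataset-class].
#' @param path file path.
#' @param zone,hemisphere projection used when reading back.
#' @return writers return \code{path} invisibly; readers a
#'   [GeoDataset-class].
#' @export
writeGeoJSON <- function(gd, path) {
  stopifnot(is(gd, "GeoDataset"))
  s <- siteTable(gd); v <- concMatrix(gd)
  feats <- lapply(seq_len(nrow(s)), function(i) {
    props <- c(list(id = s$id[i]),
               as.list(setNames(as.numeric(v[i, ]), colnames(v))))
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(s$lon[i], s$lat[i])),
         properties = props)
  })
  obj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeGeoJSON
#' @export
readGeoJSON <- function(path, zone = 34, hemisphere = "N") {
  obj <- jsonlite::read_json(path)
  stopifnot(identical(obj$type, "FeatureCollection"))
  feats <- obj$features
  lon <- vapply(feats, function(f) as.numeric(f$geometry$coordinates[[1]]), 0)
  lat <- vapply(feats, function(f) as.numeric(f$geometry$coordinates[[2]]), 0)
  props <- lapply(feats, `[[`, "properties")
  vars <- setdiff(unique(unlist(lapply(props, names))), "id")
  vals <- if (length(vars))
    do.call(rbind, lapply(props, function(p)
      vapply(vars, function(v)
        if (is.null(p[[v]])) NA_real_ else as.numeric(p[[v]]), 0)))
  else matrix(numeric(0), length(feats), 0)
  if (length(vars)) colnames(vals) <- vars
  id <- vapply(props, function(p)
    if (is.null(p$id)) NA_character_ else as.character(p$id), "")
  geoDataset(lat, lon, vals, id = id, zone = zone, hemisphere = hemisphere)
}

#' @rdname writeGeoJSON
#' @export
writeGeoCSV <- function(gd, path) {
  stopifnot(is(gd, "GeoDataset"))
  s <- siteTable(gd)
  df <- cbind(data.frame(lat = s$lat, lon = s$lon),
              as.data.frame(concMatrix(gd)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeGeoJSON
#' @export
readGeoCSV <- function(path, zone = 34, hemisphere = "N") {
  df <- read.csv(path, check.names = FALSE)
  stopifnot(all(c("lat", "lon") %in% names(df)))
  vars <- setdiff(names(df), c("lat", "lon", "id"))
  vals <- as.matrix(df[, vars, drop = FALSE])
  geoDataset(df$lat, df$lon, vals,
             id = if ("id" %in% names(df)) df$id else NULL,
             zone = zone, hemisphere = hemisphere)
}
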