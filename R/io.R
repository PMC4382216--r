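#' Read and write land-cover grids as ESRI-ASCII rasters
#'
#' The grid dialect on disk: the usual six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by
#' integer category codes 0-4, rows written north to south.
#'
#' @param path file path.
#' @return [read_landcover_asc()] returns a `landcover_grid`.
#' @export
read_landcover_asc <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  for (i in 1:6) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
  }
  body <- lapply(lines[-(1:6)], function(l)
    as.integer(strsplit(trimws(l), "\\s+")[[1]]))
  codes <- do.call(rbind, body)
  if (nrow(codes) != hdr$nrows || ncol(codes) != hdr$ncols)
    stop("parse error: grid body does not match the declared dimensions")
  codes <- codes[rev(seq_len(nrow(codes))), , drop = FALSE] # to south-up
  landcover_grid(codes, xll = hdr$xllcorner, yll = hdr$yllcorner,
                 cellsize = hdr$cellsize)
}

#' @rdname read_landcover_asc
#' @param map a `landcover_grid`.
#' @export
write_landcover_asc <- function(map, path) {
  hdr <- c(paste("ncols", ncol(map$codes)),
           paste("nrows", nrow(map$codes)),
           paste("xllcorner", map$xll),
           paste("yllcorner", map$yll),
           paste("cellsize", map$cellsize),
           "NODATA_value -9999")
  body <- apply(map$codes[rev(seq_len(nrow(map$codes))), , drop = FALSE],
                1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read and write land-cover polygon maps as GeoJSON
#'
#' Polygon features with a `category` property in
#' {natural, degraded, farmland, pasture, urban}; coordinates are planar
#' meters in the user's declared projection (written verbatim).
#'
#' @param path file path.
#' @param background background category for uncovered points.
#' @return [read_landcover_geojson()] returns a `landcover_polygons`.
#' @export
read_landcover_geojson <- function(path, background = "pasture") {
  g <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(g$features)) stop("parse error: not a FeatureCollection")
  polys <- list(); cats <- character(0)
  for (f in g$features) {
    ring <- f$geometry$coordinates[[1]]
    x <- vapply(ring, function(p) as.numeric(p[[1]]), numeric(1))
    y <- vapply(ring, function(p) as.numeric(p[[2]]), numeric(1))
    n <- length(x)
    if (x[1] == x[n] && y[1] == y[n]) { x <- x[-n]; y <- y[-n] }
    polys <- c(polys, list(simple_polygon(x, y)))
    cats <- c(cats, f$properties$category)
  }
  landcover_polygons(polys, cats, background = background)
}

#' @rdname read_landcover_geojson
#' @param map a `landcover_polygons`.
#' @export
write_landcover_geojson <- function(map, path) {
  features <- lapply(seq_along(map$polygons), function(i) {
    p <- map$polygons[[i]]
    ring <- lapply(c(seq_along(p$x), 1L), function(j) c(p$x[j], p$y[j]))
    list(type = "Feature",
         properties = list(category = map$poly_categories[i]),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write home-range polygons as a GeoJSON FeatureCollection
#'
#' One feature per polygon (MCPs, isopleth component hulls), each with the
#' supplied properties row.
#'
#' @param polygons list of `simple_polygon`.
#' @param properties data frame with one row per polygon.
#' @param path file path.
#' @export
write_polygons_geojson <- function(polygons, properties, path) {
  features <- lapply(seq_along(polygons), function(i) {
    p <- polygons[[i]]
    ring <- lapply(c(seq_along(p$x), 1L), function(j) c(p$x[j], p$y[j]))
    list(type = "Feature",
         properties = as.list(properties[i, , drop = FALSE]),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a bearings CSV
#'
#' Expected columns: `timestamp_iso` (ISO-8601, UTC assumed) or a numeric
#' `timestamp` in seconds, then `bat_id,obs1_x,obs1_y,azimuth1_deg,
#' obs2_x,obs2_y,azimuth2_deg,activity`.
#'
#' @param path file path.
#' @return data frame with a numeric `timestamp` column (seconds).
#' @export
read_bearings_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("timestamp_iso" %in% names(d)) {
    t <- as.POSIXct(d$timestamp_iso, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
    if (anyNA(t)) stop("parse error: unparseable timestamp_iso at row ",
                       which(is.na(t))[1])
    d$timestamp <- as.numeric(t)
    d$timestamp_iso <- NULL
  }
  need <- c("timestamp", "bat_id", "obs1_x", "obs1_y", "azimuth1_deg",
            "obs2_x", "obs2_y", "azimuth2_deg")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("parse error: missing columns ",
                         paste(miss, collapse = ", "))
  num <- setdiff(need, c("bat_id"))
  for (cn in num) {
    v <- suppressWarnings(as.numeric(d[[cn]]))
    if (anyNA(v)) stop("parse error: malformed value in column '", cn,
                       "' at row ", which(is.na(v))[1])
    d[[cn]] <- v
  }
  d[order(d$bat_id, d$timestamp), , drop = FALSE]
}

#' @rdname read_bearings_csv
#' @param bearings bearing table with numeric `timestamp` seconds.
#' @export
write_bearings_csv <- function(bearings, path) {
  b <- bearings
  b$timestamp_iso <- format(as.POSIXct(b$timestamp, tz = "UTC",
                                       origin = "2011-01-01"),
                            "%Y-%m-%dT%H:%M:%S")
  b$timestamp <- NULL
  utils::write.csv(
    b[, c("timestamp_iso", "bat_id", "obs1_x", "obs1_y", "azimuth1_deg",
          "obs2_x", "obs2_y", "azimuth2_deg", "activity")],
    path, row.names = FALSE)
  invisible(path)
}

#' Read/write fixes CSV (`timestamp,bat_id,session_id,x,y`)
#' @param path file path.
#' @export
read_fixes_csv <- function(path) utils::read.csv(path)

#' @rdname read_fixes_csv
#' @param fixes fixes table.
#' @export
write_fixes_csv <- function(fixes, path) {
  utils::write.csv(fixes[, c("timestamp", "bat_id", "session_id", "x", "y")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a roosts CSV (`bat_id,x,y`)
#' @param path file path.
#' @export
read_roosts_csv <- function(path) utils::read.csv(path)

#' Write a complete synthetic study to disk
#'
#' Emits the same dialects the analysis readers consume: `bearings.csv`,
#' `roosts.csv`, `landcover.asc` and a `truth.json` sidecar holding the
#' full parameterization (behaviour modes, seeds, landscape truth).
#'
#' @param study result of [generate_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_bearings_csv(study$bearings, file.path(dir, "bearings.csv"))
  utils::write.csv(study$roosts, file.path(dir, "roosts.csv"),
                   row.names = FALSE)
  write_landcover_asc(study$map, file.path(dir, "landcover.asc"))
  truth <- list(seed = study$truth$seed,
                modes = study$truth$modes,
                landscape = list(
                  config = study$truth$landscape$config,
                  patch_centers = study$truth$landscape$patch_centers,
                  patch_radii = study$truth$landscape$patch_radii),
                behaviors = lapply(study$truth$tracks, function(t)
                  t$truth$behavior[c("mode", "roost", "far_site",
                                     "step_scale", "bout_rate", "sessions")]))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
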