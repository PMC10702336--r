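# Geographic primitives: gazetteer lookup and point-in-polygon assignment.

#' Built-in country gazetteer
#'
#' A small country -> continent -> biogeographic realm table covering the
#' countries used in the package's examples and fixtures. Users can supply
#' their own gazetteer (TSV with columns `country`, `continent`, `realm`)
#' to [assign_region()].
#'
#' @param path optional TSV to read instead of the built-in table.
#' @return Tibble with columns `country`, `continent`, `realm`.
#' @export
default_gazetteer <- function(path = NULL) {
  if (!is.null(path)) {
    return(readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                           progress = FALSE))
  }
  tibble::tribble(
    ~country,        ~continent,       ~realm,
    "Germany",       "Europe",         "Palearctic",
    "Austria",       "Europe",         "Palearctic",
    "Portugal",      "Europe",         "Palearctic",
    "France",        "Europe",         "Palearctic",
    "Canada",        "North America",  "Nearctic",
    "United States", "North America",  "Nearctic",
    "Honduras",      "North America",  "Neotropic",
    "Costa Rica",    "North America",  "Neotropic",
    "Brazil",        "South America",  "Neotropic",
    "China",         "Asia",           "Palearctic",
    "India",         "Asia",           "Indomalaya",
    "Australia",     "Oceania",        "Australasia",
    "South Africa",  "Africa",         "Afrotropic",
    "Madagascar",    "Africa",         "Afrotropic"
  )
}

#' Test points against a polygon ring
#'
#' Crossing-number point-in-polygon test in lon/lat (WGS84) coordinates.
#' Points exactly on an edge or vertex count as inside (boundary-inclusive),
#' matching common shapefile practice.
#'
#' @param lon,lat numeric vectors of point coordinates.
#' @param ring two-column matrix (lon, lat) of polygon vertices; the ring
#'   may be open or closed (first vertex repeated).
#' @return Logical vector.
#' @export
point_in_ring <- function(lon, lat, ring) {
  ring <- as.matrix(ring)
  if (nrow(ring) >= 2 && all(ring[1, ] == ring[nrow(ring), ])) {
    ring <- ring[-nrow(ring), , drop = FALSE]
  }
  n <- nrow(ring)
  vapply(seq_along(lon), function(p) {
    x <- lon[[p]]; y <- lat[[p]]
    inside <- FALSE
    j <- n
    for (i in seq_len(n)) {
      xi <- ring[i, 1]; yi <- ring[i, 2]
      xj <- ring[j, 1]; yj <- ring[j, 2]
      # boundary test: point on segment (i, j)
      cross <- (xj - xi) * (y - yi) - (yj - yi) * (x - xi)
      if (abs(cross) < 1e-12 &&
          x >= min(xi, xj) - 1e-12 && x <= max(xi, xj) + 1e-12 &&
          y >= min(yi, yj) - 1e-12 && y <= max(yi, yj) + 1e-12) {
        return(TRUE)
      }
      if ((yi > y) != (yj > y)) {
        xcross <- xi + (y - yi) / (yj - yi) * (xj - xi)
        if (x < xcross) inside <- !inside
      }
      j <- i
    }
    inside
  }, logical(1))
}

#' Read polygons from a GeoJSON file
#'
#' Accepts Polygon and MultiPolygon geometries from a FeatureCollection,
#' a single Feature, or a bare geometry. Only outer rings are used (holes
#' are ignored); coordinates are lon/lat WGS84. Each polygon is named from
#' the feature's `name` property when present.
#'
#' @param path GeoJSON file.
#' @return Named list of two-column (lon, lat) matrices.
#' @export
read_polygons_geojson <- function(path) {
  g <- jsonlite::read_json(path)
  feats <- switch(g$type %||% "",
    FeatureCollection = g$features,
    Feature = list(g),
    list(list(type = "Feature", properties = list(), geometry = g))
  )
  out <- list()
  for (f in feats) {
    geom <- f$geometry
    if (is.null(geom)) next
    nm <- f$properties$name %||% paste0("polygon", length(out) + 1L)
    ring_mat <- function(ring) {
      do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
    }
    if (identical(geom$type, "Polygon")) {
      out[[nm]] <- ring_mat(geom$coordinates[[1]])
    } else if (identical(geom$type, "MultiPolygon")) {
      for (k in seq_along(geom$coordinates)) {
        key <- if (k == 1) nm else paste0(nm, "_", k)
        out[[key]] <- ring_mat(geom$coordinates[[k]][[1]])
      }
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
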