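## GeoJSON (RFC 7946) import/export of district polygon maps. Only Polygon
## geometries with a single exterior ring are supported: district maps here
## are simple planar tilings, with coordinates in arbitrary planar map units.

#' Write a district geography to GeoJSON
#'
#' Each district becomes a `Feature` with a `Polygon` geometry (exterior
#' ring, closed per RFC 7946) and `district_id` / `state_id` properties.
#'
#' @param geography a `district_geography` object.
#' @param path output file path.
#' @export
write_geojson <- function(geography, path) {
  stopifnot(inherits(geography, "district_geography"))
  feats <- lapply(geography$districts, function(d) {
    ring <- rbind(d$ring, d$ring[1, ])  # close the ring
    coords <- lapply(seq_len(nrow(ring)), function(i) c(ring[i, 1], ring[i, 2]))
    list(type = "Feature",
         properties = list(district_id = as.character(d$district_id),
                           state_id = as.character(d$state_id)),
         geometry = list(type = "Polygon", coordinates = list(coords)))
  })
  obj <- list(type = "FeatureCollection", features = unname(feats))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_geojson
#' @return `read_geojson` returns a `district_geography` object.
#' @export
read_geojson <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(obj$type, "FeatureCollection"))
    stop_config("expected a GeoJSON FeatureCollection")
  districts <- lapply(obj$features, function(f) {
    if (!identical(f$geometry$type, "Polygon"))
      stop_config("only Polygon geometries are supported (feature %s)",
                  as.character(f$properties$district_id))
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(p) c(p[[1]], p[[2]])))
    # drop closing vertex
    n <- nrow(ring)
    if (n > 1 && all(abs(ring[1, ] - ring[n, ]) < 1e-12))
      ring <- ring[-n, , drop = FALSE]
    list(district_id = as.character(f$properties$district_id),
         state_id = as.character(f$properties$state_id),
         ring = ring)
  })
  district_geography(districts)
}
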