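#' Great-circle distance between WGS84 points
#'
#' Haversine distance on a sphere of radius 6371.0088 km (IUGG mean Earth
#' radius). At HDSS scale (tens of kilometres) this agrees with ellipsoidal
#' geodesics to about half a percent.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees (vectorised,
#'   recycled to a common length).
#' @return Numeric vector of distances in kilometres.
#' @export
#' @examples
#' great_circle_km(34.0, -10.0, 34.0, -10.0018)
great_circle_km <- function(lon1, lat1, lon2, lat2) {
  check_coords(lon1, lat1)
  check_coords(lon2, lat2)
  r <- 6371.0088
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  # clamp guards rounding for near-antipodal points
  2 * r * asin(pmin(1, sqrt(a)))
}

check_coords <- function(lon, lat) {
  bad <- !is.na(lon) & !is.na(lat) &
    (lon < -180 | lon > 180 | lat < -90 | lat > 90)
  if (any(bad)) data_error("coordinates outside WGS84 range")
  invisible(TRUE)
}

#' Resolve an external place label to anchor coordinates
#'
#' Towns and cities carry a central-point coordinate; foreign countries carry
#' the coordinate of a border point nearest the surveillance area. Matching is
#' case-insensitive and whitespace-trimmed.
#'
#' @param place_label Character vector of place labels.
#' @param gazetteer Data frame with columns `label`, `kind`, `lon`, `lat`.
#' @param strict If `TRUE` (default), unknown labels raise an error; if
#'   `FALSE`, unknown labels yield `NA` coordinates so callers can exclude the
#'   move from distance-classified outputs with a logged count.
#' @return Data frame with columns `label`, `lon`, `lat`, `resolved`.
#' @export
resolve_external <- function(place_label, gazetteer, strict = TRUE) {
  stopifnot(all(c("label", "kind", "lon", "lat") %in% names(gazetteer)))
  key <- normalise_place(gazetteer$label)
  if (anyDuplicated(key)) data_error("gazetteer labels not unique")
  idx <- match(normalise_place(place_label), key)
  if (strict && anyNA(idx[!is.na(place_label)])) {
    missing <- unique(place_label[is.na(idx) & !is.na(place_label)])
    stop(errorCondition(
      sprintf("unresolved place label(s): %s", paste(missing, collapse = ", ")),
      class = c("hdssmove_unresolved_place", "hdssmove_data_error", "error")))
  }
  data.frame(label = place_label,
             lon = gazetteer$lon[idx],
             lat = gazetteer$lat[idx],
             resolved = !is.na(idx),
             stringsAsFactors = FALSE)
}

#' Bundled gazetteer of external destinations
#'
#' Malawian towns with central-point coordinates and neighbouring or common
#' destination countries anchored at the border point nearest the study area.
#'
#' @return Data frame with columns `label`, `kind`, `lon`, `lat`.
#' @export
default_gazetteer <- function() {
  path <- system.file("extdata", "gazetteer.csv", package = "hdssmove")
  utils::read.csv(path, stringsAsFactors = FALSE)
}
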