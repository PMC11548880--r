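# Great-circle geometry on the sphere (radius 6378.137 km), delegated to
# geosphere so distances and bearings agree with the conventions most
# movement-ecology analyses use.

#' Great-circle distance in kilometres
#'
#' Spherical haversine distance between two points, Earth radius
#' 6378.137 km.
#'
#' @param lat1,lon1 Coordinates of the first point, decimal degrees.
#' @param lat2,lon2 Coordinates of the second point, decimal degrees.
#'   All four arguments are recycled to a common length.
#' @return Numeric vector of distances in km.
#' @examples
#' haversine_km(0, 0, 0, 1)  # one degree of longitude at the equator
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  stopifnot(is.numeric(lat1), is.numeric(lon1), is.numeric(lat2), is.numeric(lon2))
  .check_coords(lat1, lon1)
  .check_coords(lat2, lon2)
  n <- max(length(lat1), length(lon1), length(lat2), length(lon2))
  p1 <- cbind(rep_len(lon1, n), rep_len(lat1, n))
  p2 <- cbind(rep_len(lon2, n), rep_len(lat2, n))
  as.numeric(geosphere::distHaversine(p1, p2, r = 6378137)) / 1000
}

#' Initial great-circle bearing
#'
#' Bearing from the first point towards the second along the great circle,
#' degrees clockwise from true north, in [0, 360).
#'
#' @inheritParams haversine_km
#' @return Numeric vector of bearings in degrees.
#' @export
initial_bearing <- function(lat1, lon1, lat2, lon2) {
  .check_coords(lat1, lon1)
  .check_coords(lat2, lon2)
  n <- max(length(lat1), length(lon1), length(lat2), length(lon2))
  p1 <- cbind(rep_len(lon1, n), rep_len(lat1, n))
  p2 <- cbind(rep_len(lon2, n), rep_len(lat2, n))
  if (any(p1[, 1] == p2[, 1] & p1[, 2] == p2[, 2]))
    stop("initial_bearing() is undefined for coincident points")
  b <- as.numeric(geosphere::bearing(p1, p2, a = 6378137, f = 0))  # sphere
  (b + 360) %% 360
}

#' Great-circle destination point
#'
#' Position reached from a start point after travelling a given distance on
#' a given initial bearing along the great circle.
#'
#' @param lat,lon Start coordinates, decimal degrees.
#' @param bearing Initial bearing, degrees clockwise from north.
#' @param distance_km Distance travelled, km.
#' @return A list with components `lat` and `lon` (numeric vectors).
#' @export
destination_point <- function(lat, lon, bearing, distance_km) {
  .check_coords(lat, lon)
  stopifnot(is.numeric(bearing), is.numeric(distance_km), all(distance_km >= 0))
  n <- max(length(lat), length(lon), length(bearing), length(distance_km))
  p <- cbind(rep_len(lon, n), rep_len(lat, n))
  d <- geosphere::destPoint(p, rep_len(bearing, n),
                            rep_len(distance_km, n) * 1000, r = 6378137)
  list(lat = as.numeric(d[, "lat"]), lon = as.numeric(d[, "lon"]))
}

.check_coords <- function(lat, lon) {
  if (any(!is.finite(lat)) || any(!is.finite(lon)))
    stop("coordinates must be finite")
  if (any(lat < -90 | lat > 90)) stop("latitude outside [-90, 90]")
  if (any(lon < -180 | lon > 180)) stop("longitude outside [-180, 180]")
  invisible(TRUE)
}
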