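# Spherical geodesy (Earth radius 6371.0 km) and the south-polar azimuthal
# equidistant projection used for all gridded computations. Coordinates are
# exchanged as lon/lat WGS84 decimal degrees; internal grids live on the
# projected plane in km.

EARTH_RADIUS_KM <- 6371.0

#' Great-circle distance in km
#'
#' Haversine distance on a sphere of radius 6371 km.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees. Vectorised.
#' @return Numeric vector of distances (km).
#' @export
gc_dist_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = EARTH_RADIUS_KM)
}

#' Initial great-circle bearing
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees.
#' @return Bearing in degrees true, in `[0, 360)`.
#' @export
gc_bearing <- function(lon1, lat1, lon2, lat2) {
  b <- geosphere::bearing(cbind(lon1, lat1), cbind(lon2, lat2))
  (b + 360) %% 360
}

#' Destination point along a great circle
#'
#' @param lon,lat Start coordinates (degrees).
#' @param bearing Initial bearing (degrees true).
#' @param dist_km Distance travelled (km).
#' @return Two-column matrix `lon`, `lat`.
#' @export
gc_destination <- function(lon, lat, bearing, dist_km) {
  p <- geosphere::destPoint(cbind(lon, lat), bearing, dist_km,
                            r = EARTH_RADIUS_KM)
  colnames(p) <- c("lon", "lat")
  p[, "lon"] <- ((p[, "lon"] + 180) %% 360) - 180
  p
}

#' South-polar azimuthal equidistant projection
#'
#' Projects lon/lat to plane coordinates (km) centred on the South Pole:
#' the radial coordinate is the meridional arc distance from the pole, so
#' meridional distances are exact and zonal distortion is small near the
#' pole. The y axis points along the prime meridian, x along 90degE.
#'
#' @param lon,lat Degrees.
#' @return Two-column matrix `x`, `y` in km.
#' @export
polar_xy <- function(lon, lat) {
  r <- (lat + 90) * pi / 180 * EARTH_RADIUS_KM
  cbind(x = r * sin(lon * pi / 180), y = r * cos(lon * pi / 180))
}

#' Inverse of [polar_xy()]
#'
#' @param x,y Projected coordinates (km).
#' @return Two-column matrix `lon`, `lat` in degrees.
#' @export
polar_lonlat <- function(x, y) {
  r <- sqrt(x^2 + y^2)
  lat <- r / EARTH_RADIUS_KM * 180 / pi - 90
  lon <- ifelse(r < 1e-9, 0, atan2(x, y) * 180 / pi)
  cbind(lon = lon, lat = lat)
}

#' Circular mean and mean resultant length
#'
#' Summary of a sample of directions: the circular mean heading and the
#' mean resultant length rho = |n^-1 sum exp(i theta)|, which is 1 for
#' perfectly concentrated and 0 for balanced (e.g. uniform) samples.
#'
#' @param angles_deg Numeric vector of angles in degrees. `NA` removed.
#' @return List with `mean_deg` (in `[0, 360)`) and `rho` (in `[0, 1]`).
#' @export
circular_summary <- function(angles_deg) {
  angles_deg <- angles_deg[!is.na(angles_deg)]
  if (length(angles_deg) == 0L) stop("circular_summary: no angles supplied")
  a <- angles_deg * pi / 180
  s <- mean(sin(a)); c <- mean(cos(a))
  list(mean_deg = (atan2(s, c) * 180 / pi + 360) %% 360,
       rho = sqrt(s^2 + c^2))
}

# Smallest signed angular difference a - b in (-180, 180].
angle_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}
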