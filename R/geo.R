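# Great-circle geometry. One sphere radius is used everywhere in the package.

#' Earth radius used throughout (km)
#'
#' Mean Earth radius of the IUGG sphere, 6371.0088 km. All great-circle
#' distances in the package are haversine distances on this sphere.
#' @export
EARTH_RADIUS_KM <- 6371.0088

#' Great-circle distance between points (km)
#'
#' Haversine distance on a sphere of radius [EARTH_RADIUS_KM].
#'
#' @param lon1,lat1 Numeric vectors, degrees east / degrees north.
#' @param lon2,lat2 Numeric vectors (recycled), degrees.
#' @return Numeric vector of distances in km.
#' @export
gc_dist_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = EARTH_RADIUS_KM)
}

#' Great-circle distance matrix (km)
#'
#' @param p1,p2 Two-column matrices (lon, lat) in degrees.
#' @return A `nrow(p1)` x `nrow(p2)` matrix of distances in km.
#' @export
gc_dist_matrix <- function(p1, p2) {
  geosphere::distm(p1, p2,
                   fun = function(x, y) geosphere::distHaversine(x, y, r = EARTH_RADIUS_KM))
}

# km spanned by one degree of a great circle on the package sphere
km_per_degree <- function() EARTH_RADIUS_KM * pi / 180
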