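# Plain-text I/O for the pipeline's data: long-format CSV for gridded
# fields, two-column CSV for time series, and the population table.

#' Write a climate field to CSV (long format)
#'
#' One row per node/cell with columns `lon`, `lat`, `value`, plus constant
#' columns `var` and `time_ka`.
#'
#' @param field A [climate_field].
#' @param path Output file path.
#' @export
write_field_csv <- function(field, path) {
  if (inherits(field$grid, "grid_spec")) {
    g <- field$grid
    df <- data.frame(lon = rep(g$lon, length(g$lat)),
                     lat = rep(g$lat, each = length(g$lon)),
                     value = as.numeric(field$values))
  } else {
    co <- field_point_coords(field$grid)
    df <- data.frame(lon = co[, 1], lat = co[, 2],
                     value = as.numeric(field$values))
  }
  df$var <- field$var
  df$time_ka <- field$time_ka
  utils::write.csv(df, path, row.names = FALSE)
}

#' Read a climate field from CSV (long format)
#'
#' Reconstructs a regular grid when the (lon, lat) rows form a complete
#' grid in column-major order, otherwise returns the field on the point set.
#'
#' @param path CSV file written by [write_field_csv].
#' @return A [climate_field].
#' @export
read_field_csv <- function(path) {
  df <- utils::read.csv(path)
  lon_u <- sort(unique(df$lon)); lat_u <- sort(unique(df$lat))
  if (nrow(df) == length(lon_u) * length(lat_u) &&
      identical(df$lon, rep(lon_u, length(lat_u))) &&
      identical(df$lat, rep(lat_u, each = length(lon_u)))) {
    g <- grid_spec(lon_u, lat_u)
    v <- matrix(df$value, length(lon_u))
  } else {
    g <- cbind(df$lon, df$lat)
    v <- df$value
  }
  climate_field(v, g, var = df$var[1], time_ka = df$time_ka[1])
}

#' Write / read a (time_ka, value) series as CSV
#'
#' Used for the sea-level and CO2 curves.
#'
#' @param series Data frame with columns `time_ka`, `value`.
#' @param path File path.
#' @export
write_series_csv <- function(series, path) {
  utils::write.csv(series[, c("time_ka", "value")], path, row.names = FALSE)
}

#' @rdname write_series_csv
#' @export
read_series_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("time_ka", "value") %in% names(df)))
  df
}

#' Write / read a population table as CSV
#'
#' @param table Population data frame (see [make_population_table]).
#' @param path File path.
#' @export
write_population_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
}

#' @rdname write_population_csv
#' @export
read_population_csv <- function(path) {
  df <- utils::read.csv(path)
  df$freshwater_adjacent <- as.logical(df$freshwater_adjacent)
  df
}
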