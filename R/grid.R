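# Gridded climate containers: regular lon/lat grids and point sets, plus the
# shape-preserving regrid operator used by every downscaling step.

#' Regular longitude/latitude grid specification
#'
#' @param lon,lat Strictly increasing numeric vectors of cell-centre
#'   coordinates in degrees. Longitudes must lie in `[-180, 360)`; grids that
#'   cross the antimeridian are not supported.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(lon, lat) {
  stopifnot(is.numeric(lon), is.numeric(lat), length(lon) >= 2, length(lat) >= 2)
  if (any(diff(lon) <= 0) || any(diff(lat) <= 0))
    stop("grid axes must be strictly increasing")
  if (any(lon < -180 | lon >= 360)) stop("longitudes must lie in [-180, 360)")
  if (any(lat < -90 | lat > 90)) stop("latitudes must lie in [-90, 90]")
  structure(list(lon = as.numeric(lon), lat = as.numeric(lat)), class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells, lon [%g, %g], lat [%g, %g]\n",
              length(x$lon), length(x$lat),
              min(x$lon), max(x$lon), min(x$lat), max(x$lat)))
  invisible(x)
}

#' One gridded climate variable at one time label
#'
#' A `climate_field` holds a single variable (precipitation in mm/yr,
#' temperature in degrees C, Koeppen aridity, or elevation in m) either on a
#' regular [grid_spec] (values as an `nlon x nlat` matrix) or on an arbitrary
#' point set such as a [build_hex_grid] grid (values as a vector).
#'
#' @param values Numeric matrix (`nlon x nlat`, regular grid) or vector
#'   (point set).
#' @param grid A [grid_spec], a `hex_grid`, or a two-column matrix/data.frame
#'   of (lon, lat) point coordinates.
#' @param var Variable tag, e.g. `"precip"`, `"temp"`, `"aridity"`,
#'   `"elevation"`.
#' @param time_ka Time label in ka before present (optional).
#' @return An object of class `climate_field`.
#' @export
climate_field <- function(values, grid, var = "precip", time_ka = NA_real_) {
  if (inherits(grid, "grid_spec")) {
    values <- as.matrix(values)
    if (!all(dim(values) == c(length(grid$lon), length(grid$lat))))
      stop("values must be an nlon x nlat matrix matching the grid")
  } else {
    co <- field_point_coords(grid)
    values <- as.numeric(values)
    if (length(values) != nrow(co))
      stop("values length must match the number of grid points")
  }
  if (identical(var, "precip") && any(values < 0, na.rm = TRUE))
    stop("precipitation must be non-negative")
  structure(list(values = values, grid = grid, var = var,
                 time_ka = time_ka), class = "climate_field")
}

#' @export
print.climate_field <- function(x, ...) {
  n <- length(x$values)
  cat(sprintf("<climate_field> var=%s t=%s ka, %d values [%g, %g]\n",
              x$var, format(x$time_ka), n,
              suppressWarnings(min(x$values, na.rm = TRUE)),
              suppressWarnings(max(x$values, na.rm = TRUE))))
  invisible(x)
}

# coordinates of a point-set grid as a two-column (lon, lat) matrix
field_point_coords <- function(grid) {
  if (inherits(grid, "hex_grid")) return(cbind(grid$nodes$lon, grid$nodes$lat))
  if (is.data.frame(grid)) return(cbind(grid$lon, grid$lat))
  if (is.matrix(grid) && ncol(grid) == 2) return(grid)
  stop("unsupported grid object")
}

# --- Fritsch-Carlson (PCHIP) tensor interpolation ---------------------------
#
# The regrid operator must be continuously differentiable, reproduce constants
# and linear data, and not overshoot the local data range (the role Akima-type
# interpolants play for climate fields). Fritsch-Carlson monotone cubic
# Hermite slopes give exactly these properties; the two axes are handled as a
# tensor product. Slopes follow the classic weighted-harmonic-mean rule with
# shape-preserving one-sided endpoint slopes.

# slopes for every column of Y at nodes x; Y is length(x) x m
fc_slopes <- function(x, Y) {
  n <- length(x)
  m <- ncol(Y)
  if (n == 2) {                      # linear fallback at two nodes
    d <- (Y[2, , drop = FALSE] - Y[1, , drop = FALSE]) / (x[2] - x[1])
    return(rbind(d, d))
  }
  h <- diff(x)                                        # n-1
  delta <- (Y[-1, , drop = FALSE] - Y[-n, , drop = FALSE]) / h   # (n-1) x m
  D <- matrix(0, n, m)
  # interior: weighted harmonic mean where secants share a sign
  if (n > 2) {
    i <- 2:(n - 1)
    d1 <- delta[i - 1, , drop = FALSE]
    d2 <- delta[i, , drop = FALSE]
    w1 <- 2 * h[i] + h[i - 1]
    w2 <- h[i] + 2 * h[i - 1]
    same <- (d1 * d2) > 0
    den <- w1 / d1 + w2 / d2
    Di <- matrix(0, length(i), m)
    Di[same] <- ((w1 + w2)[row(Di)] / den)[same]
    D[i, ] <- Di
  }
  D[1, ] <- fc_endpoint(h[1], h[2], delta[1, ], delta[2, ])
  D[n, ] <- fc_endpoint(h[n - 1], h[n - 2], delta[n - 1, ], delta[n - 2, ])
  D
}

# shape-preserving three-point endpoint slope
fc_endpoint <- function(h1, h2, del1, del2) {
  d <- ((2 * h1 + h2) * del1 - h1 * del2) / (h1 + h2)
  d[sign(d) != sign(del1)] <- 0
  big <- (sign(del1) != sign(del2)) & (abs(d) > 3 * abs(del1))
  d[big] <- 3 * del1[big]
  d
}

# evaluate the Hermite interpolant of every column of Y at shared query xi;
# returns length(xi) x ncol(Y)
pchip_multi <- function(x, Y, xi) {
  Y <- as.matrix(Y)
  D <- fc_slopes(x, Y)
  idx <- findInterval(xi, x, rightmost.closed = TRUE)
  idx[idx < 1] <- 1L
  idx[idx >= length(x)] <- length(x) - 1L
  h <- x[idx + 1] - x[idx]
  t <- (xi - x[idx]) / h
  h00 <- (1 + 2 * t) * (1 - t)^2
  h10 <- t * (1 - t)^2
  h01 <- t^2 * (3 - 2 * t)
  h11 <- t^2 * (t - 1)
  h00 * Y[idx, , drop = FALSE] + (h * h10) * D[idx, , drop = FALSE] +
    h01 * Y[idx + 1, , drop = FALSE] + (h * h11) * D[idx + 1, , drop = FALSE]
}

# evaluate column k of Y at its own query xi[k]; returns length(xi) vector
pchip_diag <- function(x, Y, xi) {
  Y <- as.matrix(Y)
  stopifnot(ncol(Y) == length(xi))
  D <- fc_slopes(x, Y)
  idx <- findInterval(xi, x, rightmost.closed = TRUE)
  idx[idx < 1] <- 1L
  idx[idx >= length(x)] <- length(x) - 1L
  h <- x[idx + 1] - x[idx]
  t <- (xi - x[idx]) / h
  k <- seq_along(xi)
  y0 <- Y[cbind(idx, k)]; y1 <- Y[cbind(idx + 1L, k)]
  d0 <- D[cbind(idx, k)]; d1 <- D[cbind(idx + 1L, k)]
  (1 + 2 * t) * (1 - t)^2 * y0 + h * t * (1 - t)^2 * d0 +
    t^2 * (3 - 2 * t) * y1 + h * t^2 * (t - 1) * d1
}

#' Regrid a climate field (the downscaling interpolation operator)
#'
#' Interpolates a field on a regular [grid_spec] onto a finer grid or onto an
#' arbitrary point set, using a tensor-product shape-preserving cubic Hermite
#' (Fritsch-Carlson/PCHIP) scheme: continuously differentiable, exact for
#' constant and (bi)linear data, and free of overshoots beyond the local data
#' range.
#'
#' @param field A [climate_field] on a regular grid.
#' @param target A [grid_spec], `hex_grid`, or two-column (lon, lat) matrix.
#' @return A [climate_field] on `target` with the same `var` and `time_ka`.
#' @export
regrid <- function(field, target) {
  stopifnot(inherits(field, "climate_field"))
  if (!inherits(field$grid, "grid_spec"))
    stop("regrid requires a source field on a regular grid")
  g <- field$grid
  V <- field$values
  if (inherits(target, "grid_spec")) {
    tl <- target$lon; tp <- target$lat
    check_hull(g, tl, tp)
    W <- pchip_multi(g$lon, V, tl)          # ntlon x nlat
    out <- t(pchip_multi(g$lat, t(W), tp))  # ntlon x ntlat
  } else {
    co <- field_point_coords(target)
    check_hull(g, co[, 1], co[, 2])
    A <- pchip_multi(g$lon, V, co[, 1])     # npts x nlat
    out <- pchip_diag(g$lat, t(A), co[, 2])
  }
  if (identical(field$var, "precip")) out <- pmax(out, 0)
  climate_field(out, target, var = field$var, time_ka = field$time_ka)
}

check_hull <- function(g, lon, lat, tol = 1e-9) {
  if (any(lon < min(g$lon) - tol | lon > max(g$lon) + tol) ||
      any(lat < min(g$lat) - tol | lat > max(g$lat) + tol))
    stop("target nodes fall outside the source grid hull; ",
         "extrapolation is not supported (see fill_submarine_cells)")
  invisible(TRUE)
}
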