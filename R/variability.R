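# Decadal-scale variability: turn 30-year climatological normals into 100
# decadal fields per millennium using annual-resolution simulation series,
# and compute the Koeppen aridity index.

#' Decadal scalers from a 1000-year annual series
#'
#' For each decade `d = 1..100` of a millennium, compares the decadal mean to
#' the mean of the 30-year window formed by decades `d-1, d, d+1`.
#' Precipitation mode returns the ratio of means (dimensionless, so a
#' constant series gives 1); temperature mode returns the difference of means
#' (degrees C, so a constant series gives 0). At the millennium edges
#' (`d = 1`, `d = 100`) the window is clamped to the available years — annual
#' series of successive millennia are simulated independently and cannot be
#' stitched.
#'
#' @param series Numeric matrix `n_cells x 1000` (or 3-D array with 1000 as
#'   the last dimension) of annual values on the coarse grid.
#' @param mode `"precip"` (ratio) or `"temp"` (difference).
#' @param floor Lower guard for 30-year precipitation means (mm/yr), as in
#'   the multiplicative delta methods.
#' @return Matrix `n_cells x 100` of scalers, with attribute `mode`.
#' @export
decadal_scalers <- function(series, mode = c("precip", "temp"), floor = 0.1) {
  mode <- match.arg(mode)
  if (is.array(series) && length(dim(series)) == 3)
    series <- matrix(series, ncol = dim(series)[3])
  series <- as.matrix(series)
  n_yr <- ncol(series)
  if (n_yr != 1000) stop("annual series must have exactly 1000 years")
  W <- decade_weights(n_yr)
  dec <- series %*% W$dec
  win <- series %*% W$win
  out <- if (mode == "precip") dec / pmax(win, floor) else dec - win
  attr(out, "mode") <- mode
  out
}

# 1000 x 100 weight matrices: decadal means and clamped 30-year window means
decade_weights <- function(n_yr = 1000) {
  n_dec <- n_yr / 10
  dec <- matrix(0, n_yr, n_dec)
  win <- matrix(0, n_yr, n_dec)
  for (d in seq_len(n_dec)) {
    yrs <- ((d - 1) * 10 + 1):(d * 10)
    dec[yrs, d] <- 1 / length(yrs)
    w <- max(1, (d - 2) * 10 + 1):min(n_yr, (d + 1) * 10)
    win[w, d] <- 1 / length(w)
  }
  list(dec = dec, win = win)
}

#' Apply decadal scalers to a climatological normal
#'
#' Produces the 100 decadal fields of a millennium from its 30-year normal:
#' precipitation is multiplied by the ratio scalers (and clipped at zero),
#' temperature is offset by the difference scalers. The scalers must already
#' be regridded to the normal's grid (see [regrid_scalers]).
#'
#' @param normal [climate_field] (or numeric vector) of the climatological
#'   normal on the analysis grid.
#' @param scalers Matrix `n_nodes x 100` of scalers on the same grid.
#' @param mode `"precip"` or `"temp"`; defaults to the scaler attribute.
#' @return Matrix `n_nodes x 100` of decadal values.
#' @export
apply_scalers <- function(normal, scalers, mode = NULL) {
  if (is.null(mode)) mode <- attr(scalers, "mode")
  mode <- match.arg(mode, c("precip", "temp"))
  v <- if (inherits(normal, "climate_field")) normal$values else normal
  v <- as.numeric(v)
  if (length(v) != nrow(scalers))
    stop("normal and scalers are on different grids")
  out <- if (mode == "precip") pmax(v * scalers, 0) else v + scalers
  out
}

#' Regrid a set of decadal scalers to the analysis grid
#'
#' @param scalers Matrix `n_cells x 100` on the coarse grid (as returned by
#'   [decadal_scalers]).
#' @param coarse_grid [grid_spec] of the coarse grid.
#' @param target Target grid ([grid_spec], `hex_grid`, or point matrix).
#' @return Matrix `n_target x 100`, carrying over the `mode` attribute.
#' @export
regrid_scalers <- function(scalers, coarse_grid, target) {
  mode <- attr(scalers, "mode")
  cols <- lapply(seq_len(ncol(scalers)), function(d) {
    f <- climate_field(matrix(scalers[, d], length(coarse_grid$lon)),
                       coarse_grid, var = "scaler")
    as.numeric(regrid(f, target)$values)
  })
  out <- do.call(cbind, cols)
  if (identical(mode, "precip")) out <- pmax(out, 0)
  attr(out, "mode") <- mode
  out
}

#' Koeppen aridity index
#'
#' The ratio of annual precipitation (mm) to mean annual temperature
#' (degrees C) plus a constant of 33: `A = P / (T + 33)`. Lower values are
#' more arid. Undefined for temperatures at or below -33 degrees C.
#'
#' @param precip,temp Numeric vectors/matrices of matching shape, or
#'   [climate_field]s on the same grid.
#' @return Aridity values with the shape of the inputs (a [climate_field] if
#'   the inputs were fields).
#' @export
koppen_aridity <- function(precip, temp) {
  as_field <- inherits(precip, "climate_field")
  p <- if (as_field) precip$values else precip
  t <- if (inherits(temp, "climate_field")) temp$values else temp
  if (!all(dim(as.matrix(p)) == dim(as.matrix(t))))
    stop("precip and temp must have the same shape")
  if (any(t <= -33, na.rm = TRUE))
    stop("aridity index undefined for temperatures <= -33 degrees C")
  a <- p / (t + 33)
  if (as_field)
    return(climate_field(a, precip$grid, var = "aridity",
                         time_ka = precip$time_ka))
  a
}
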