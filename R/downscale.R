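# Delta-method downscaling and bias correction, submarine-cell infilling, and
# sea-level-dependent land masks.

#' Pick the reference snapshot time by CO2 matching
#'
#' The dynamic delta method corrects the coarse simulation at time `t` with
#' the fine-resolution snapshot whose global CO2 concentration is closest to
#' the CO2 at `t`, relaxing the stationarity assumption of the classical
#' delta method. Ties are broken toward the more recent snapshot.
#'
#' @param co2 Data frame with columns `time_ka`, `value` (ppm).
#' @param t Analysis time (ka before present); must be a time of `co2`.
#' @param snapshot_times Times (ka) at which fine snapshots exist; all must be
#'   times of `co2`.
#' @return The selected snapshot time (ka).
#' @export
select_reference_time <- function(co2, t, snapshot_times) {
  if (length(snapshot_times) == 0) stop("snapshot_times is empty")
  v_t <- series_value(co2, t)
  v_s <- vapply(snapshot_times, function(s) series_value(co2, s), 0)
  d <- abs(v_s - v_t)
  ord <- order(d, snapshot_times)     # ties -> smaller ka (more recent)
  snapshot_times[ord[1]]
}

#' Look up a value in a (time_ka, value) series
#'
#' Exact time matches are returned as stored; other times within the series
#' coverage are linearly interpolated. Times outside the coverage are an
#' error.
#'
#' @param series Data frame with columns `time_ka` and `value`.
#' @param t Time (ka) at which to evaluate.
#' @return Numeric value.
#' @export
series_value <- function(series, t) {
  tt <- series$time_ka
  hit <- which(abs(tt - t) < 1e-9)
  if (length(hit)) return(series$value[hit[1]])
  if (t < min(tt) || t > max(tt))
    stop(sprintf("time %g ka outside series coverage [%g, %g]", t, min(tt), max(tt)))
  stats::approx(tt, series$value, xout = t)$y
}

# guarded correction ratio for the multiplicative delta methods: denominators
# are floored (hyperarid cells) and the ratio is capped to bound noise
# amplification
delta_ratio <- function(num, den, floor = 0.1, cap = 100) {
  pmin(num / pmax(den, floor), cap)
}

#' Dynamic delta-method downscaling
#'
#' Downscales a coarse field at time `t` to the fine grid using a fine
#' snapshot at the CO2-matched reference time `t_hat` as a time-dependent
#' correction term. Multiplicative (precipitation):
#' `regrid(coarse_t) * fine_that / regrid(coarse_that)`; additive
#' (temperature): `regrid(coarse_t) + (fine_that - regrid(coarse_that))`.
#' Multiplicative denominators are floored at `ratio_floor` and correction
#' ratios capped at `ratio_cap`; multiplicative output is clipped at zero.
#'
#' @param coarse_t,coarse_that [climate_field]s on the same coarse grid, at
#'   the analysis and reference times.
#' @param fine_that [climate_field] on the fine grid at the reference time.
#' @param mode `"multiplicative"` or `"additive"`.
#' @param ratio_floor,ratio_cap Guard parameters for the multiplicative mode.
#' @return A [climate_field] on the fine grid at `coarse_t$time_ka`.
#' @export
dynamic_delta <- function(coarse_t, coarse_that, fine_that,
                          mode = c("multiplicative", "additive"),
                          ratio_floor = 0.1, ratio_cap = 100) {
  mode <- match.arg(mode)
  if (!same_grid(coarse_t$grid, coarse_that$grid))
    stop("coarse_t and coarse_that must share a grid")
  ct <- regrid(coarse_t, fine_that$grid)
  cth <- regrid(coarse_that, fine_that$grid)
  out <- if (mode == "multiplicative") {
    pmax(ct$values * delta_ratio(fine_that$values, cth$values,
                                 ratio_floor, ratio_cap), 0)
  } else {
    ct$values + (fine_that$values - cth$values)
  }
  climate_field(out, fine_that$grid, var = coarse_t$var,
                time_ka = coarse_t$time_ka)
}

#' Classical delta-method bias correction
#'
#' Corrects a model field at time `t` against present-day observations on the
#' target (analysis) grid. Multiplicative:
#' `regrid(model_t) * obs_0 / regrid(model_0)`; additive:
#' `regrid(model_t) + (obs_0 - regrid(model_0))`.
#'
#' @param model_t,model_0 [climate_field]s on the same model grid at time `t`
#'   and at present.
#' @param obs_0 Present-day observed [climate_field] on the target grid.
#' @param mode `"multiplicative"` or `"additive"`.
#' @param ratio_floor,ratio_cap Guard parameters as in [dynamic_delta].
#' @return A [climate_field] on the grid of `obs_0` at `model_t$time_ka`.
#' @export
classical_delta <- function(model_t, model_0, obs_0,
                            mode = c("multiplicative", "additive"),
                            ratio_floor = 0.1, ratio_cap = 100) {
  mode <- match.arg(mode)
  if (!same_grid(model_t$grid, model_0$grid))
    stop("model_t and model_0 must share a grid")
  mt <- regrid(model_t, obs_0$grid)
  m0 <- regrid(model_0, obs_0$grid)
  out <- if (mode == "multiplicative") {
    pmax(mt$values * delta_ratio(obs_0$values, m0$values,
                                 ratio_floor, ratio_cap), 0)
  } else {
    mt$values + (obs_0$values - m0$values)
  }
  climate_field(out, obs_0$grid, var = model_t$var, time_ka = model_t$time_ka)
}

same_grid <- function(a, b) {
  if (inherits(a, "grid_spec") && inherits(b, "grid_spec"))
    return(isTRUE(all.equal(a$lon, b$lon)) && isTRUE(all.equal(a$lat, b$lat)))
  identical(a, b)
}

#' Sea-level-dependent land mask
#'
#' A node is land at time `t` iff its present-day elevation strictly exceeds
#' the sea level `s(t)`. Lower sea level therefore exposes a superset of the
#' land exposed at higher sea level (nesting).
#'
#' @param elev [climate_field] of elevation (m), or a numeric vector/matrix.
#' @param sea Data frame with columns `time_ka`, `value` (sea level in m
#'   relative to present, `s(0) = 0`).
#' @param t Time (ka) within the coverage of `sea`.
#' @return Logical vector/matrix of the same shape as the elevations, with
#'   attributes `time_ka` and `sea_level_m`.
#' @export
land_mask <- function(elev, sea, t) {
  s <- series_value(sea, t)
  e <- if (inherits(elev, "climate_field")) elev$values else elev
  m <- e > s
  attr(m, "time_ka") <- t
  attr(m, "sea_level_m") <- s
  m
}

#' Fill exposed submarine cells by inverse-distance weighting
#'
#' Delta-method corrections are undefined at nodes that are below present-day
#' sea level (no observed climatology) but exposed as land at a past time.
#' Such nodes receive the inverse-distance-weighted mean of the `k` nearest
#' donor nodes, using great-circle distances; donor values are unchanged.
#'
#' @param field [climate_field] on a point-set grid (e.g. a `hex_grid`).
#' @param donors Logical vector: nodes that carry a valid delta-method value
#'   (typically the present-day land mask).
#' @param targets Logical vector: nodes to fill (typically land at time `t`
#'   but submarine today). Nodes that are both donor and target are treated
#'   as donors.
#' @param k Number of nearest donors (default 4).
#' @param power IDW exponent (default 2).
#' @return A [climate_field] with target nodes filled.
#' @export
fill_submarine_cells <- function(field, donors, targets, k = 4, power = 2) {
  stopifnot(inherits(field, "climate_field"))
  co <- field_point_coords(field$grid)
  donors <- as.logical(donors); targets <- as.logical(targets)
  targets <- targets & !donors
  if (!any(donors)) stop("no donor nodes")
  if (!any(targets)) return(field)
  v <- field$values
  dmat <- gc_dist_matrix(co[targets, , drop = FALSE], co[donors, , drop = FALSE])
  dv <- v[donors]
  kk <- min(k, ncol(dmat))
  fill <- apply(dmat, 1, function(d) {
    nb <- order(d)[seq_len(kk)]
    dd <- d[nb]
    if (any(dd < 1e-9)) return(dv[nb[which.min(dd)]])
    w <- 1 / dd^power
    sum(w * dv[nb]) / sum(w)
  })
  v[targets] <- fill
  climate_field(v, field$grid, var = field$var, time_ka = field$time_ka)
}
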