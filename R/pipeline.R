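# End-to-end convenience wrappers: coarse simulation -> analysis-grid
# normals -> decadal fields, as the acceptance script and vignette run them.

#' Two-step delta-method chain to the analysis grid
#'
#' Runs the full downscaling chain for one variable at one analysis time:
#' CO2-matched reference time, dynamic delta (coarse -> fine grid,
#' multiplicative for precipitation / additive for temperature), classical
#' delta against the present-day observed climatology (fine -> hex grid),
#' and inverse-distance infilling of nodes that are land at time `t` but
#' below present-day sea level.
#'
#' @param world A `synthetic_world`.
#' @param t Analysis time (ka), one of `world$times`.
#' @param var `"precip"` or `"temp"`.
#' @return A [climate_field] on the world's hex grid.
#' @export
downscale_chain <- function(world, t, var = c("precip", "temp")) {
  var <- match.arg(var)
  mode <- if (var == "precip") "multiplicative" else "additive"
  snaps <- world$snapshot_times
  cs <- world$coarse_series
  step1 <- function(tt) {
    that <- select_reference_time(world$co2, tt, snaps)
    dynamic_delta(cs[[as.character(tt)]][[var]],
                  cs[[as.character(that)]][[var]],
                  world$fine_snapshots[[as.character(that)]][[var]], mode)
  }
  f_t <- step1(t)
  f_0 <- step1(0)
  out <- classical_delta(f_t, f_0, world$observed[[var]], mode)
  donors <- world$hex$nodes$elev > 0
  exposed <- land_mask(world$elevation, world$sea_level, t) & !donors
  fill_submarine_cells(out, donors, exposed)
}

#' Decadal fields for one millennium on the analysis grid
#'
#' Computes the 100 decadal scalers from the annual series of the
#' CO2-matched snapshot millennium, regrids them to the hex grid, and
#' applies them to the millennium's climatological normal. For `"aridity"`,
#' decadal precipitation and temperature fields are combined through the
#' Koeppen index.
#'
#' @param world A `synthetic_world`.
#' @param t Analysis time (ka), one of `world$times`.
#' @param var `"precip"`, `"temp"`, or `"aridity"`.
#' @return Matrix `n_nodes x 100` of decadal values.
#' @export
decadal_fields <- function(world, t, var = c("precip", "temp", "aridity")) {
  var <- match.arg(var)
  if (var == "aridity")
    return(koppen_aridity(decadal_fields(world, t, "precip"),
                          decadal_fields(world, t, "temp")))
  # scaler millennium: CO2-matched within the annual-series coverage
  that <- select_reference_time(world$co2, t,
                                as.numeric(names(world$annual_series)))
  mode <- if (var == "precip") "precip" else "temp"
  sc <- decadal_scalers(world$annual_series[[as.character(that)]][[var]],
                        mode = mode)
  sc_hex <- regrid_scalers(sc, world$coarse_grid, world$hex)
  apply_scalers(world$normals[[as.character(t)]][[var]], sc_hex, mode)
}
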