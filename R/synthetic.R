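# Synthetic-world generator: a fully self-consistent set of pipeline inputs
# (coarse series, fine snapshots, annual series, observed climatology,
# elevation, bathymetric strait, sea level, CO2, populations) with planted,
# analytically known ground truth for the corridor, strait, and tolerance
# stages.

#' Configuration for the synthetic world
#'
#' Defaults emulate the shapes of the real inputs at desk scale: a
#' 3.75 x 2.5 degree coarse grid, a 1.25 x 0.83 degree fine grid with nine
#' snapshot times, 1000-year annual series per snapshot millennium, a
#' quasi-hexagonal analysis grid over 15-70E / 5-43N, an oscillating sea
#' level with s(0) = 0, a smooth CO2 curve, a bathymetric strait with a known
#' trench geometry, and a population table with a planted precipitation
#' floor.
#'
#' @param ... Named overrides of any default listed below.
#' @return A list of configuration values.
#' @export
world_config <- function(...) {
  cfg <- list(
    # grids
    coarse_lon = seq(7.5, 75, by = 3.75),
    coarse_lat = seq(-2.5, 47.5, by = 2.5),
    fine_lon = seq(13.75, 71.25, by = 1.25),
    fine_lat = seq(3.5, 44.5, by = 0.83),
    hex_window = c(15, 70, 5, 43),
    hex_spacing_km = 140,
    # times
    n_millennia = 8,
    snapshot_times = c(0, 3, 6, 8, 10, 12, 15, 18, 21),
    n_annual = 1000,
    # sea level s(t) = -amp * (1 - cos(2 pi t / period)), so s(0) = 0
    sea_amp = 60, sea_period = 20,
    # planted corridor bottlenecks (mm/yr) per analysis millennium
    bottleneck_north = NULL,   # default 100 + 8 t
    bottleneck_south = NULL,   # default 130 + 6 t
    barrier_value = 20,
    # strait bathymetry: perpendicular-distance channel profile
    strait_window = c(42.5, 44.5, 11.5, 13.5),
    strait_cell_deg = 0.01,
    strait_centre = c(43.4, 12.6),
    trench_halfwidth_km = 1.2,
    trench_floor_m = -110,
    flank_slope_m_per_km = 12.5,
    # populations
    n_populations = 50,
    precip_floor = 90,
    n_freshwater = 3,
    temp_ref = 20)
  over <- list(...)
  stopifnot(all(names(over) %in% names(cfg)))
  cfg[names(over)] <- over
  if (is.null(cfg$bottleneck_north))
    cfg$bottleneck_north <- 100 + 8 * (seq_len(cfg$n_millennia) - 1)
  if (is.null(cfg$bottleneck_south))
    cfg$bottleneck_south <- 130 + 6 * (seq_len(cfg$n_millennia) - 1)
  cfg
}

# band-limited random surface: sum of low-order cosine modes over the domain
smooth_surface <- function(n_modes = 6, kmax = 3) {
  a <- stats::rnorm(n_modes, 0, 1 / sqrt(n_modes))
  kx <- sample(0:kmax, n_modes, replace = TRUE)
  ky <- sample(0:kmax, n_modes, replace = TRUE)
  phx <- stats::runif(n_modes, 0, 2 * pi)
  phy <- stats::runif(n_modes, 0, 2 * pi)
  function(lon, lat) {
    u <- (lon - 7.5) / 70
    w <- (lat + 2.5) / 50
    out <- 0
    for (m in seq_len(n_modes))
      out <- out + a[m] * cos(2 * pi * kx[m] * u + phx[m]) *
        cos(2 * pi * ky[m] * w + phy[m])
    out
  }
}

#' Analytic sea-crossing width of the synthetic strait (km)
#'
#' The synthetic strait has a V-with-flat-floor cross-section: a flat trench
#' of half-width `hw` at elevation `floor_m`, with flanks rising at `slope`
#' m per km. The open-water gap at sea level `s` is
#' `2 * (hw + (s - floor_m) / slope)` for `s >= floor_m` and 0 below (the
#' trench floor is exposed and forms a land bridge).
#'
#' @param s Sea level (m, relative to present).
#' @param config A [world_config] list (uses the `trench_*`/`flank_*`
#'   entries).
#' @return Gap width in km.
#' @export
strait_gap_true <- function(s, config = world_config()) {
  ifelse(s < config$trench_floor_m, 0,
         2 * (config$trench_halfwidth_km +
                (s - config$trench_floor_m) / config$flank_slope_m_per_km))
}

# synthetic bathymetry raster: channel of the configured profile running
# NW-SE through the strait centre, land rising on both sides
make_bathymetry <- function(cfg, roughness) {
  g <- grid_spec(seq(cfg$strait_window[1], cfg$strait_window[2],
                     by = cfg$strait_cell_deg),
                 seq(cfg$strait_window[3], cfg$strait_window[4],
                     by = cfg$strait_cell_deg))
  cen <- cfg$strait_centre
  kx <- km_per_degree() * cos(cen[2] * pi / 180)
  ky <- km_per_degree()
  dx <- outer((g$lon - cen[1]) * kx, rep(1, length(g$lat)))
  dy <- outer(rep(1, length(g$lon)), (g$lat - cen[2]) * ky)
  # signed perpendicular distance (km) to the NW-SE channel axis
  d <- abs((dx + dy) / sqrt(2))
  elev <- pmin(cfg$trench_floor_m +
                 pmax(d - cfg$trench_halfwidth_km, 0) * cfg$flank_slope_m_per_km,
               400)
  # gentle relief far from the channel, well above any sea level
  far <- d > 60
  rough <- roughness(rep(g$lon, length(g$lat)),
                     rep(g$lat, each = length(g$lon)))
  elev[far] <- elev[far] + 50 * rough[far]
  climate_field(elev, g, var = "elevation")
}

#' Plant a climatic corridor with a known bottleneck into a field
#'
#' Overwrites a hex-grid field so that the maximin (bottleneck) path value
#' between the ends of `path_nodes` is exactly `bottleneck`: along the path,
#' values ramp upward from `bottleneck` away from a single bottleneck cell
#' (placed ~60% along the path), and every cell off the path (and not in
#' `keep`) is capped at `barrier_value`, so every alternative path contains
#' a cell at or below the barrier.
#'
#' @param field [climate_field] on a `hex_grid`.
#' @param path_nodes Integer node indices forming a chain of adjacent nodes.
#' @param bottleneck Planted bottleneck value, in `[0, 1000]` for
#'   precipitation.
#' @param barrier_value Cap for off-path cells; must be `< bottleneck`.
#' @param keep Node indices left untouched (e.g. another planted corridor).
#' @return The modified [climate_field].
#' @export
plant_corridor <- function(field, path_nodes, bottleneck, barrier_value,
                           keep = integer(0)) {
  stopifnot(inherits(field, "climate_field"), inherits(field$grid, "hex_grid"))
  if (bottleneck < 0 || bottleneck > 1000)
    stop("planted bottleneck outside [0, 1000]")
  if (barrier_value >= bottleneck)
    stop("barrier_value must be below the bottleneck")
  grid <- field$grid
  if (length(path_nodes) > 1) {
    ok <- vapply(seq_len(length(path_nodes) - 1), function(i)
      path_nodes[i + 1] %in% grid$adj[[path_nodes[i]]], logical(1))
    if (!all(ok)) stop("path_nodes are not a chain of adjacent nodes")
  }
  v <- field$values
  off <- setdiff(seq_along(v), c(path_nodes, keep))
  # compress (not flat-cap) the background into (0, barrier]: preserves the
  # smooth seeded relief while guaranteeing every off-path cell <= barrier
  hi <- max(v[off], barrier_value)
  v[off] <- pmin(v[off], barrier_value * pmax(v[off], 0) / hi)
  pin <- max(1L, round(0.6 * length(path_nodes)))
  ramp <- bottleneck + 2 * abs(seq_along(path_nodes) - pin)
  v[path_nodes] <- ramp
  climate_field(v, grid, var = field$var, time_ka = field$time_ka)
}

#' Synthetic ethnographic population table with a planted tolerance floor
#'
#' Non-freshwater populations have annual precipitation at or above `floor`,
#' with the minimum attained exactly once; `n_freshwater` populations are
#' flagged as residing close to freshwater sources and placed below the
#' floor (they are not constrained by rainfall). Residence temperatures are
#' drawn near `temp_ref`, and precipitation gaps are arranged so the Koeppen
#' aridity floor is attained by the same population:
#' `floor / (temp_ref + 33)`.
#'
#' @param n Total number of populations (>= 1).
#' @param floor Planted precipitation floor (mm/yr, >= 0).
#' @param n_freshwater Number of flagged populations (`< n`).
#' @param seed Optional RNG seed.
#' @param temp_ref Residence temperature of the floor population (degrees C).
#' @return Data frame with columns `id`, `precip_mm_yr`, `temp_c`,
#'   `aridity`, `freshwater_adjacent`.
#' @export
make_population_table <- function(n, floor = 90, n_freshwater = 3,
                                  seed = NULL, temp_ref = 20) {
  if (n < 1) stop("n must be at least 1")
  if (floor < 0) stop("floor must be non-negative")
  if (n_freshwater >= n) stop("n_freshwater must be smaller than n")
  if (!is.null(seed)) set.seed(seed)
  n_dry <- n - n_freshwater
  # gap above the floor keeps the aridity minimum at the floor population
  # despite +/- 2 degC temperature scatter: P >= floor + floor * 4 / (temp_ref + 31)
  gap <- floor * 4 / (temp_ref + 31) + 1
  precip <- c(floor, floor + gap + stats::rexp(n_dry - 1, rate = 1 / 120))
  temp <- c(temp_ref, temp_ref + stats::runif(n_dry - 1, -2, 2))
  if (n_freshwater > 0) {
    precip <- c(precip, stats::runif(n_freshwater, 0.3 * floor,
                                     max(0.9 * floor, 1e-6)))
    temp <- c(temp, temp_ref + stats::runif(n_freshwater, -2, 2))
  }
  flag <- c(rep(FALSE, n_dry), rep(TRUE, n_freshwater))
  data.frame(id = sprintf("pop%03d", seq_len(n)),
             precip_mm_yr = precip, temp_c = temp,
             aridity = precip / (temp + 33),
             freshwater_adjacent = flag)
}

#' Generate a synthetic world with planted ground truth
#'
#' Builds every input the pipeline needs — smooth band-limited climate
#' fields on the coarse and fine grids, per-millennium 1000-year annual
#' series, a present-day observed climatology, a hex analysis grid with
#' elevation, a bathymetric strait, sea-level and CO2 curves, and a
#' population table — plus planted structures whose downstream answers are
#' known exactly: a northern and a southern corridor with configured
#' bottlenecks per millennium (the northern path runs through the Sinai
#' land-bridge box, the southern through the strait exemption zone), a
#' strait trench with an analytic gap-width law, and a population
#' precipitation floor. Same seed, same world, bit for bit.
#'
#' @param config A [world_config] list.
#' @param seed Integer RNG seed.
#' @return An object of class `synthetic_world`; see the fields in the
#'   implementation and the methods vignette.
#' @export
make_world <- function(config = world_config(), seed = 1) {
  cfg <- config
  if (cfg$n_millennia < 1) stop("n_millennia must be at least 1")
  if (any(cfg$bottleneck_north < 0 | cfg$bottleneck_north > 1000) ||
      any(cfg$bottleneck_south < 0 | cfg$bottleneck_south > 1000))
    stop("planted bottleneck outside [0, 1000] mm/yr")
  stopifnot(length(cfg$bottleneck_north) == cfg$n_millennia,
            length(cfg$bottleneck_south) == cfg$n_millennia)
  set.seed(seed)

  times <- seq_len(cfg$n_millennia) - 1
  snaps <- cfg$snapshot_times
  all_t <- sort(unique(c(times, snaps)))
  coarse_grid <- grid_spec(cfg$coarse_lon, cfg$coarse_lat)
  fine_grid <- grid_spec(cfg$fine_lon, cfg$fine_lat)

  # deterministic global curves with seeded phases
  ph <- stats::runif(6, 0, 2 * pi)
  co2 <- data.frame(time_ka = 0:max(all_t),
                    value = 240 + 35 * cos(2 * pi * (0:max(all_t)) / 41 + ph[1]) +
                      12 * sin(2 * pi * (0:max(all_t)) / 13.5 + ph[2]))
  sea <- data.frame(time_ka = 0:max(all_t),
                    value = -cfg$sea_amp *
                      (1 - cos(2 * pi * (0:max(all_t)) / cfg$sea_period)))

  # continuous climate surfaces: coarse-scale base, fine-scale detail,
  # observational pattern
  P_base <- smooth_surface(); P_detail <- smooth_surface(8, 8)
  P_obs_pat <- smooth_surface(8, 6)
  T_base <- smooth_surface(); T_detail <- smooth_surface(8, 8)
  T_obs_pat <- smooth_surface(8, 6)
  p_mod <- function(t) 1 + 0.25 * sin(2 * pi * t / 41 + ph[3]) +
    0.08 * sin(2 * pi * t / 19 + ph[4])
  t_mod <- function(t) 3 * sin(2 * pi * t / 41 + ph[5])
  P_fun <- function(lon, lat, t, detail = TRUE, obs = FALSE) {
    v <- (300 + 120 * P_base(lon, lat)) * p_mod(t)
    if (detail) v <- v * (1 + 0.15 * P_detail(lon, lat))
    if (obs) v <- v * (1 + 0.10 * P_obs_pat(lon, lat))
    pmax(v, 0)
  }
  T_fun <- function(lon, lat, t, detail = TRUE, obs = FALSE) {
    v <- 12 + 10 * T_base(lon, lat) + t_mod(t)
    if (detail) v <- v + 1.5 * T_detail(lon, lat)
    if (obs) v <- v + 1.0 * T_obs_pat(lon, lat)
    v
  }
  eval_grid <- function(f, g, t, ...) {
    lo <- rep(g$lon, length(g$lat)); la <- rep(g$lat, each = length(g$lon))
    matrix(f(lo, la, t, ...), length(g$lon))
  }

  coarse_series <- lapply(all_t, function(t) list(
    precip = climate_field(eval_grid(P_fun, coarse_grid, t, detail = FALSE),
                           coarse_grid, "precip", t),
    temp = climate_field(eval_grid(T_fun, coarse_grid, t, detail = FALSE),
                         coarse_grid, "temp", t)))
  names(coarse_series) <- as.character(all_t)

  fine_snapshots <- lapply(snaps, function(t) list(
    precip = climate_field(eval_grid(P_fun, fine_grid, t), fine_grid,
                           "precip", t),
    temp = climate_field(eval_grid(T_fun, fine_grid, t), fine_grid,
                         "temp", t)))
  names(fine_snapshots) <- as.character(snaps)

  # 1000-year annual series per snapshot millennium: AR(1) multiplicative
  # (precip) / additive (temp) interannual variability around the millennium
  # climatology
  ncell <- length(coarse_grid$lon) * length(coarse_grid$lat)
  ar1 <- function(n_yr, phi = 0.7, sd_innov = sqrt(1 - 0.7^2)) {
    Z <- matrix(0, ncell, n_yr)
    Z[, 1] <- stats::rnorm(ncell)
    for (i in 2:n_yr) Z[, i] <- phi * Z[, i - 1] + sd_innov * stats::rnorm(ncell)
    Z
  }
  annual_series <- lapply(times, function(t) {
    base_p <- as.numeric(coarse_series[[as.character(t)]]$precip$values)
    base_t <- as.numeric(coarse_series[[as.character(t)]]$temp$values)
    list(precip = base_p * exp(0.08 * ar1(cfg$n_annual)),
         temp = base_t + 0.6 * ar1(cfg$n_annual))
  })
  names(annual_series) <- as.character(times)

  # analysis grid with smooth elevation (basins included)
  E_pat <- smooth_surface(8, 4)
  hex <- build_hex_grid(cfg$hex_window, cfg$hex_spacing_km,
                        elevation = function(lon, lat) 250 + 350 * E_pat(lon, lat))

  # observed present-day climatology on the hex grid
  observed <- list(
    precip = climate_field(P_fun(hex$nodes$lon, hex$nodes$lat, 0, obs = TRUE),
                           hex, "precip", 0),
    temp = climate_field(T_fun(hex$nodes$lon, hex$nodes$lat, 0, obs = TRUE),
                         hex, "temp", 0))

  # routes and planted corridor paths
  routes <- list(northern = route_spec("northern"),
                 southern = route_spec("southern"),
                 unrestricted = route_spec("unrestricted"))
  start <- routes$unrestricted$start
  is_end <- function(lon, lat) lon > 65 | lat > 37
  path_n <- walk_path(hex, start, list(c(31.5, 22), c(33.8, 30.2), c(36, 44)),
                      is_end)
  path_s <- walk_path(hex, start, list(c(43.4, 12.6), c(50, 16), c(71, 18)),
                      is_end)
  hex$nodes$elev[c(path_n, path_s)] <-
    pmax(hex$nodes$elev[c(path_n, path_s)], 150)

  # hex-grid climatological normals with both corridors planted
  normals <- vector("list", cfg$n_millennia)
  truth_rows <- list()
  for (i in seq_along(times)) {
    t <- times[i]
    p0 <- climate_field(P_fun(hex$nodes$lon, hex$nodes$lat, t, obs = TRUE),
                        hex, "precip", t)
    tv <- T_fun(hex$nodes$lon, hex$nodes$lat, t, obs = TRUE)
    tv[c(path_n, path_s)] <- pmin(pmax(tv[c(path_n, path_s)], 12), 26)
    tf <- climate_field(tv, hex, "temp", t)
    f1 <- plant_corridor(p0, path_n, cfg$bottleneck_north[i],
                         cfg$barrier_value, keep = path_s)
    f2 <- plant_corridor(p0, path_s, cfg$bottleneck_south[i],
                         cfg$barrier_value, keep = path_n)
    v <- f1$values
    v[path_s] <- f2$values[path_s]
    shared <- intersect(path_n, path_s)
    v[shared] <- pmax(f1$values[shared], f2$values[shared])
    pf <- climate_field(v, hex, "precip", t)
    af <- koppen_aridity(pf, tf)
    normals[[i]] <- list(precip = pf, temp = tf, aridity = af)
    truth_rows[[i]] <- data.frame(
      time_ka = t,
      route = c("northern", "southern"),
      bottleneck_precip = c(cfg$bottleneck_north[i], cfg$bottleneck_south[i]),
      bottleneck_aridity = c(min(af$values[path_n]), min(af$values[path_s])))
  }
  names(normals) <- as.character(times)

  bathy <- make_bathymetry(cfg, E_pat)
  truth <- list(
    corridor = do.call(rbind, truth_rows),
    strait = data.frame(sea_level_m = sea$value,
                        gap_km = strait_gap_true(sea$value, cfg)),
    precip_floor = cfg$precip_floor,
    aridity_floor = cfg$precip_floor / (cfg$temp_ref + 33))

  populations <- make_population_table(cfg$n_populations, cfg$precip_floor,
                                       cfg$n_freshwater,
                                       temp_ref = cfg$temp_ref)

  structure(list(
    config = cfg, seed = seed, times = times, snapshot_times = snaps,
    coarse_grid = coarse_grid, fine_grid = fine_grid, hex = hex,
    coarse_series = coarse_series, fine_snapshots = fine_snapshots,
    annual_series = annual_series, observed = observed, normals = normals,
    elevation = climate_field(hex$nodes$elev, hex, "elevation", 0),
    bathymetry = bathy, sea_level = sea, co2 = co2,
    populations = populations, routes = routes,
    paths = list(northern = path_n, southern = path_s),
    truth = truth), class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_world> seed %d: %d millennia, %d snapshots, ",
                     "%d hex nodes, %d populations\n"),
              x$seed, length(x$times), length(x$snapshot_times),
              nrow(x$hex$nodes), nrow(x$populations)))
  invisible(x)
}
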