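# Quasi-uniform hexagonal analysis grid and route specifications for the
# out-of-Africa corridor analysis.

#' Build a quasi-uniform hexagonal grid over a geographic window
#'
#' Nodes are laid out in offset rows (hexagonal packing): rows are spaced
#' `sqrt(3)/2 * spacing` apart in latitude, nodes within a row are `spacing`
#' apart along the parallel, and alternate rows are shifted by half a step,
#' so each interior node has ~6 neighbours at roughly the target spacing.
#' Two nodes are adjacent iff their great-circle distance is at most the
#' grid's maximum internode spacing.
#'
#' @param window Numeric `c(lon_min, lon_max, lat_min, lat_max)` in degrees;
#'   default the analysis window 15-70E, 5-43N.
#' @param spacing_km Target internode spacing in km (default 55).
#' @param elevation Optional node elevations: a function `f(lon, lat)` in m,
#'   a [climate_field] on a regular grid (sampled by [regrid]), or a numeric
#'   constant. Default 0.
#' @param max_spacing_factor Adjacency radius as a multiple of `spacing_km`
#'   (default 1.2): the maximum internode spacing of the grid.
#' @return An object of class `hex_grid`: `nodes` (data frame with `lon`,
#'   `lat`, `elev`), `adj` (adjacency list of node indices), `edges`
#'   (two-column matrix), `spacing_km`, `max_spacing_km`, `window`.
#' @export
build_hex_grid <- function(window = c(15, 70, 5, 43), spacing_km = 55,
                           elevation = NULL, max_spacing_factor = 1.2) {
  if (spacing_km <= 0) stop("spacing_km must be positive")
  if (window[2] <= window[1] || window[4] <= window[3])
    stop("degenerate window")
  dlat <- spacing_km * sqrt(3) / 2 / km_per_degree()
  lats <- seq(window[3], window[4], by = dlat)
  pts <- vector("list", length(lats))
  for (i in seq_along(lats)) {
    la <- lats[i]
    dlon <- spacing_km / (km_per_degree() * cos(la * pi / 180))
    off <- if (i %% 2 == 0) dlon / 2 else 0
    lo <- seq(window[1] + off, window[2], by = dlon)
    pts[[i]] <- cbind(lon = lo, lat = la, row = i)
  }
  pts <- do.call(rbind, pts)
  nodes <- data.frame(lon = pts[, 1], lat = pts[, 2])
  n <- nrow(nodes)
  max_sp <- max_spacing_factor * spacing_km

  # adjacency: only same-row and adjacent-row pairs can be within reach
  row_id <- pts[, 3]
  edges <- vector("list", max(row_id))
  for (r in seq_len(max(row_id))) {
    a <- which(row_id == r)
    b <- which(row_id == r | row_id == r + 1)
    d <- gc_dist_matrix(cbind(nodes$lon[a], nodes$lat[a]),
                        cbind(nodes$lon[b], nodes$lat[b]))
    hit <- which(d <= max_sp & d > 1e-9, arr.ind = TRUE)
    if (nrow(hit)) {
      e <- cbind(a[hit[, 1]], b[hit[, 2]])
      edges[[r]] <- e[e[, 1] < e[, 2], , drop = FALSE]
    }
  }
  edges <- do.call(rbind, edges)
  adj <- rep(list(integer(0)), n)
  if (!is.null(edges) && nrow(edges)) {
    both <- rbind(edges, edges[, 2:1])
    adj <- unname(split(both[, 2], factor(both[, 1], levels = seq_len(n))))
    adj <- lapply(adj, as.integer)
  }

  nodes$elev <- if (is.null(elevation)) 0 else
    if (is.function(elevation)) elevation(nodes$lon, nodes$lat) else
    if (inherits(elevation, "climate_field"))
      as.numeric(regrid(elevation, cbind(nodes$lon, nodes$lat))$values) else
    rep_len(as.numeric(elevation), n)

  structure(list(nodes = nodes, adj = adj, edges = edges,
                 spacing_km = spacing_km, max_spacing_km = max_sp,
                 window = window),
            class = "hex_grid")
}

#' @export
print.hex_grid <- function(x, ...) {
  cat(sprintf("<hex_grid> %d nodes, target spacing %g km (max %g km), window [%g,%g]x[%g,%g]\n",
              nrow(x$nodes), x$spacing_km, x$max_spacing_km,
              x$window[1], x$window[2], x$window[3], x$window[4]))
  invisible(x)
}

#' Nearest grid node to a coordinate
#'
#' @param grid A `hex_grid`.
#' @param lon,lat Coordinate in degrees.
#' @return Node index.
#' @export
nearest_node <- function(grid, lon, lat) {
  which.min(gc_dist_km(grid$nodes$lon, grid$nodes$lat, lon, lat))
}

#' Median nearest-neighbour spacing of a hex grid (km)
#'
#' @param grid A `hex_grid`.
#' @return Median over nodes of the distance to the nearest adjacent node.
#' @export
median_spacing_km <- function(grid) {
  d <- gc_dist_km(grid$nodes$lon[grid$edges[, 1]], grid$nodes$lat[grid$edges[, 1]],
                  grid$nodes$lon[grid$edges[, 2]], grid$nodes$lat[grid$edges[, 2]])
  nn <- rep(Inf, nrow(grid$nodes))
  for (k in seq_along(d)) {
    i <- grid$edges[k, 1]; j <- grid$edges[k, 2]
    if (d[k] < nn[i]) nn[i] <- d[k]
    if (d[k] < nn[j]) nn[j] <- d[k]
  }
  stats::median(nn[is.finite(nn)])
}

#' Route specification for corridor analysis
#'
#' Defines the start point, the exit region, and the geometry that isolates
#' the northern (Nile-Sinai land bridge) or southern (Strait of Bab
#' al-Mandab) route: removed barrier cells, the strait exemption zone where
#' neither sea level nor climate constraints apply (southern route; the
#' strait is assumed crossable), and the Nile delta polygon assumed crossable
#' at all times.
#'
#' @param route `"northern"`, `"southern"`, or `"unrestricted"`.
#' @param start Start coordinate, default `c(32.6, 10.2)` (lon E, lat N).
#' @param end_lon,end_lat Exit predicate: a node is outside Africa if
#'   `lon > end_lon` or `lat > end_lat` (defaults 65E / 37N).
#' @param strait_centre Centre of the Bab al-Mandab strait, default
#'   `c(43.4, 12.6)`.
#' @param strait_radius_km Radius of the strait exemption zone (default 40).
#' @param nile_delta Always-suitable box `c(lon_min, lon_max, lat_min,
#'   lat_max)`, default `c(30.5, 32.5, 29.5, 31.6)`; `NULL` disables it.
#' @param sinai_barrier Box removed for the southern analysis (blocks the
#'   land bridge), default `c(32.6, 35.5, 29, 31.5)`.
#' @return An object of class `route_spec`.
#' @export
route_spec <- function(route = c("unrestricted", "northern", "southern"),
                       start = c(32.6, 10.2), end_lon = 65, end_lat = 37,
                       strait_centre = c(43.4, 12.6), strait_radius_km = 40,
                       nile_delta = c(30.5, 32.5, 29.5, 31.6),
                       sinai_barrier = c(32.6, 35.5, 29, 31.5)) {
  route <- match.arg(route)
  structure(list(route = route, start = start, end_lon = end_lon,
                 end_lat = end_lat, strait_centre = strait_centre,
                 strait_radius_km = strait_radius_km,
                 nile_delta = nile_delta, sinai_barrier = sinai_barrier),
            class = "route_spec")
}

in_box <- function(lon, lat, box) {
  if (is.null(box)) return(rep(FALSE, length(lon)))
  lon >= box[1] & lon <= box[2] & lat >= box[3] & lat <= box[4]
}

#' Resolve a route specification on a hex grid
#'
#' Computes the node sets a route implies: the start node, the exit nodes,
#' the removed barrier nodes (the passage of the other route), the strait
#' exemption nodes, and the always-suitable Nile delta nodes. Barrier and
#' exemption sets are disjoint by construction (barriers win).
#'
#' @param route A [route_spec].
#' @param grid A `hex_grid`.
#' @return List with `start` (index), `is_end`, `barrier`, `exempt`,
#'   `always` (logical vectors over nodes).
#' @export
route_nodes <- function(route, grid) {
  lon <- grid$nodes$lon; lat <- grid$nodes$lat
  # the zone must capture at least one node and sever the adjacency, so it
  # is never narrower than the grid's maximum internode spacing
  r_eff <- max(route$strait_radius_km, grid$max_spacing_km)
  in_strait <- gc_dist_km(lon, lat, route$strait_centre[1],
                          route$strait_centre[2]) <= r_eff
  barrier <- switch(route$route,
    northern = in_strait,                     # close the southern passage
    southern = in_box(lon, lat, route$sinai_barrier),  # close the land bridge
    unrestricted = rep(FALSE, length(lon)))
  exempt <- if (route$route %in% c("southern", "unrestricted"))
    in_strait & !barrier else rep(FALSE, length(lon))
  always <- in_box(lon, lat, route$nile_delta) & !barrier
  start <- nearest_node(grid, route$start[1], route$start[2])
  is_end <- lon > route$end_lon | lat > route$end_lat
  if (is_end[start]) stop("start node lies in the exit region")
  list(start = start, is_end = is_end, barrier = barrier,
       exempt = exempt, always = always)
}

#' Trace a node path through waypoints on a hex grid
#'
#' Greedy walk used by the synthetic-world generator to plant corridors:
#' from the node nearest `from`, repeatedly steps to the adjacent node
#' closest to the current waypoint, advancing through the waypoints in order.
#' The walk stops at the first node satisfying `end_predicate`; the last
#' waypoint should lie at or beyond the exit region so the walk keeps moving
#' toward it.
#'
#' @param grid A `hex_grid`.
#' @param from `c(lon, lat)` start coordinate.
#' @param waypoints List of `c(lon, lat)` targets visited in order.
#' @param end_predicate Function of (lon, lat) returning logical; the walk
#'   stops at the first node satisfying it.
#' @param max_steps Safety bound on the path length.
#' @return Integer vector of node indices forming a chain of adjacent nodes.
#' @export
walk_path <- function(grid, from, waypoints, end_predicate, max_steps = 5000) {
  cur <- nearest_node(grid, from[1], from[2])
  path <- cur
  gi <- 1
  for (step in seq_len(max_steps)) {
    if (end_predicate(grid$nodes$lon[cur], grid$nodes$lat[cur])) return(path)
    g <- waypoints[[gi]]
    if (gi < length(waypoints) &&
        gc_dist_km(grid$nodes$lon[cur], grid$nodes$lat[cur], g[1], g[2]) <=
          0.7 * grid$spacing_km) {
      gi <- gi + 1
      g <- waypoints[[gi]]
    }
    nb <- setdiff(grid$adj[[cur]], path)
    if (!length(nb)) nb <- grid$adj[[cur]]
    d <- gc_dist_km(grid$nodes$lon[nb], grid$nodes$lat[nb], g[1], g[2])
    cur <- nb[which.min(d)]
    path <- c(path, cur)
  }
  stop("walk_path did not reach its goal within max_steps")
}
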