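# Sea-crossing width of a strait: connected landmass labelling on a
# bathymetric raster, pairwise landmass distances, and the minimax-path
# crossing distance between Africa and the Arabian Peninsula.

#' Label connected landmasses at a given sea level
#'
#' Cells with elevation strictly above the sea level are partitioned into
#' 8-connected components. Two seed coordinates identify the African and
#' Arabian landmasses.
#'
#' @param bathy [climate_field] of elevation/bathymetry (m) on a regular
#'   grid.
#' @param sea_level Sea level in m relative to present (negative = lower).
#' @param seeds List with elements `africa` and `arabia`, each `c(lon, lat)`.
#' @return Object of class `landmass_labels`: `labels` (integer matrix, `NA`
#'   on water), `n`, `sizes`, `africa`, `arabia` (component ids), `grid`,
#'   `sea_level`.
#' @export
label_landmasses <- function(bathy, sea_level,
                             seeds = list(africa = c(42.8, 11.6),
                                          arabia = c(43.3, 13.0))) {
  stopifnot(inherits(bathy, "climate_field"), inherits(bathy$grid, "grid_spec"))
  g <- bathy$grid
  land <- bathy$values > sea_level
  nx <- length(g$lon); ny <- length(g$lat)
  id <- matrix(seq_len(nx * ny), nx, ny)
  edge_list <- list()
  shifts <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))
  for (s in shifts) {
    i1 <- seq_len(nx - abs(s[1])) + if (s[1] < 0) abs(s[1]) else 0L
    j1 <- seq_len(ny - abs(s[2])) + if (s[2] < 0) abs(s[2]) else 0L
    i2 <- i1 + s[1]; j2 <- j1 + s[2]
    a <- as.vector(id[i1, j1, drop = FALSE])
    b <- as.vector(id[i2, j2, drop = FALSE])
    keep <- land[a] & land[b]
    edge_list[[length(edge_list) + 1]] <- cbind(a[keep], b[keep])
  }
  edges <- do.call(rbind, edge_list)
  gg <- igraph::graph_from_edgelist(edges, directed = FALSE)
  gg <- igraph::add_vertices(gg, nx * ny - igraph::vcount(gg))
  memb <- igraph::components(gg)$membership
  labels <- matrix(memb, nx, ny)
  labels[!land] <- NA_integer_
  # renumber land components 1..K by decreasing size
  tab <- sort(table(labels), decreasing = TRUE)
  remap <- stats::setNames(seq_along(tab), names(tab))
  labels[] <- remap[as.character(labels)]
  seed_comp <- function(pt) {
    i <- which.min(abs(g$lon - pt[1])); j <- which.min(abs(g$lat - pt[2]))
    lab <- labels[i, j]
    if (is.na(lab)) stop("seed coordinate is submarine at this sea level")
    lab
  }
  structure(list(labels = labels, n = length(tab),
                 sizes = as.integer(tab),
                 africa = unname(seed_comp(seeds$africa)),
                 arabia = unname(seed_comp(seeds$arabia)),
                 grid = g, sea_level = sea_level),
            class = "landmass_labels")
}

#' Minimum great-circle distances between landmasses
#'
#' For each unordered pair of landmasses, the minimum great-circle distance
#' between their cell centres — the complete landmass graph. Only boundary
#' cells (land cells with a water or raster-edge neighbour) enter the
#' search.
#'
#' @param labels A `landmass_labels` object.
#' @return Object of class `landmass_graph`: symmetric weight matrix `w`
#'   (km, zero diagonal) plus the `africa`/`arabia` component ids.
#' @export
landmass_distances <- function(labels) {
  lb <- labels$labels
  g <- labels$grid
  nx <- nrow(lb); ny <- ncol(lb)
  land <- !is.na(lb)
  # boundary: land cell with at least one non-land 8-neighbour or on the edge
  pad <- matrix(FALSE, nx + 2, ny + 2)
  pad[2:(nx + 1), 2:(ny + 1)] <- land
  nbsum <- matrix(0L, nx, ny)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    nbsum <- nbsum + pad[2:(nx + 1) + di, 2:(ny + 1) + dj]
  }
  boundary <- land & (nbsum < 8L)
  K <- labels$n
  w <- matrix(0, K, K)
  coords <- lapply(seq_len(K), function(k) {
    idx <- which(boundary & lb == k, arr.ind = TRUE)
    cbind(g$lon[idx[, 1]], g$lat[idx[, 2]])
  })
  if (K > 1) {
    for (a in 1:(K - 1)) for (b in (a + 1):K) {
      d <- min(gc_dist_matrix(coords[[a]], coords[[b]]))
      w[a, b] <- d; w[b, a] <- d
    }
  }
  structure(list(w = w, africa = labels$africa, arabia = labels$arabia),
            class = "landmass_graph")
}

#' Minimax sea-crossing distance between Africa and Arabia
#'
#' Solves the minmax path problem on the complete landmass graph: the path
#' between the African and Arabian landmasses that minimises the maximum
#' edge weight (the longest single water hop), allowing stepping-stone
#' islands. Zero when both seeds lie on one landmass. Uses the classical
#' equivalence with the minimum spanning tree: the minimax path value equals
#' the largest edge on the MST path between the two nodes.
#'
#' @param graph A `landmass_graph` (see [landmass_distances]).
#' @return List with `distance_km` and the component ids of the path.
#' @export
minimax_crossing <- function(graph) {
  a <- graph$africa; b <- graph$arabia
  if (is.na(a) || is.na(b)) stop("Africa/Arabia labels missing")
  if (a == b) return(list(distance_km = 0, path = a))
  g <- igraph::graph_from_adjacency_matrix(graph$w, mode = "undirected",
                                           weighted = TRUE)
  tr <- igraph::mst(g, weights = igraph::E(g)$weight)
  sp <- igraph::shortest_paths(tr, from = a, to = b, output = "epath")
  ew <- igraph::E(tr)$weight[as.integer(sp$epath[[1]])]
  vp <- igraph::shortest_paths(tr, from = a, to = b)$vpath[[1]]
  list(distance_km = max(ew), path = as.integer(vp))
}

#' Sea-crossing distance through time
#'
#' Reconstructs, for each requested time, the land configuration from the
#' bathymetry and the sea-level series, and computes the minimax crossing
#' distance between the African and Arabian landmasses. As sea level falls
#' the land masks nest, so the crossing distance is non-increasing.
#'
#' @param bathy Elevation/bathymetry [climate_field] on a regular grid.
#' @param sea Data frame `time_ka`, `value` (m) covering all `times`.
#' @param times Numeric vector of times (ka).
#' @param seeds Africa/Arabia seed coordinates (see [label_landmasses]).
#' @return Data frame with columns `time_ka`, `sea_level_m`, `crossing_km`.
#' @export
crossing_series <- function(bathy, sea, times,
                            seeds = list(africa = c(42.8, 11.6),
                                         arabia = c(43.3, 13.0))) {
  res <- lapply(times, function(t) {
    s <- series_value(sea, t)
    lm <- label_landmasses(bathy, s, seeds)
    d <- if (lm$africa == lm$arabia) 0 else
      minimax_crossing(landmass_distances(lm))$distance_km
    data.frame(time_ka = t, sea_level_m = s, crossing_km = d)
  })
  do.call(rbind, res)
}
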