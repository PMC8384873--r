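# Shared fixtures and independent brute-force oracles. All fixtures are
# built in code; the oracles deliberately use different algorithms (and,
# where possible, different libraries) from the implementation they check.

# small world: one millennium, modest grids -- fast enough to regenerate
light_config <- function(...) {
  world_config(n_millennia = 1, snapshot_times = c(0, 11, 21),
               hex_spacing_km = 140, ...)
}

# tiny rectangular "hex" grid (degenerate square lattice) for exhaustive
# path enumeration: spacing chosen so lateral+diagonal neighbours connect
tiny_grid <- function(nx = 6, ny = 5, lon0 = 30, lat0 = 10, step = 0.5) {
  lon <- rep(lon0 + (seq_len(nx) - 1) * step, ny)
  lat <- rep(lat0 + (seq_len(ny) - 1) * step, each = nx)
  n <- nx * ny
  co <- cbind(lon, lat)
  d <- gc_dist_matrix(co, co)
  max_sp <- max(d[d <= 1.5 * step * 111.2 & d > 0])  # 8-neighbourhood
  adj <- lapply(seq_len(n), function(i) which(d[i, ] <= max_sp & d[i, ] > 0))
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    j <- adj[[i]][adj[[i]] > i]
    if (length(j)) cbind(i, j)
  }))
  structure(list(nodes = data.frame(lon = lon, lat = lat, elev = 100),
                 adj = adj, edges = edges, spacing_km = step * 111.2,
                 max_spacing_km = max_sp,
                 window = c(lon0, lon0 + nx * step, lat0, lat0 + ny * step)),
            class = "hex_grid")
}

# route over a tiny grid: start at the west edge, exit past the east edge,
# no zones
tiny_route <- function(grid) {
  n <- nrow(grid$nodes)
  list(start = which.min(grid$nodes$lon + grid$nodes$lat),
       is_end = grid$nodes$lon >= max(grid$nodes$lon) - 1e-9,
       barrier = rep(FALSE, n), exempt = rep(FALSE, n),
       always = rep(FALSE, n))
}

# exhaustive maximin over all simple paths (DFS with sound pruning: a branch
# whose running minimum cannot beat the best path found so far is abandoned);
# independent of the threshold-sweep implementation
brute_maximin <- function(values, grid, route) {
  best <- -Inf
  n <- nrow(grid$nodes)
  visited <- logical(n)
  dfs <- function(i, cur_min) {
    if (cur_min <= best) return(invisible())
    if (route$is_end[i]) {
      best <<- cur_min
      return(invisible())
    }
    for (j in grid$adj[[i]]) {
      if (!visited[j]) {
        visited[j] <<- TRUE
        dfs(j, min(cur_min, values[j]))
        visited[j] <<- FALSE
      }
    }
  }
  visited[route$start] <- TRUE
  dfs(route$start, values[route$start])
  if (is.infinite(best)) NA_real_ else best
}

# independent connectivity oracle via igraph components on the suitable
# subgraph (path_exists itself is a hand-rolled frontier BFS)
igraph_path_exists <- function(suitable, grid, route) {
  if (!suitable[route$start]) return(FALSE)
  keep <- which(suitable)
  e <- grid$edges
  e <- e[suitable[e[, 1]] & suitable[e[, 2]], , drop = FALSE]
  idx <- match(seq_len(nrow(grid$nodes)), keep)
  g <- igraph::make_empty_graph(n = length(keep), directed = FALSE)
  if (nrow(e)) g <- igraph::add_edges(g, t(cbind(idx[e[, 1]], idx[e[, 2]])))
  memb <- igraph::components(g)$membership
  s <- memb[idx[route$start]]
  ends <- idx[which(route$is_end & suitable)]
  length(ends) > 0 && any(memb[ends] == s)
}

# flood-fill connected-component labelling of a land matrix (8-connected),
# independent of the igraph-based implementation
flood_label <- function(land) {
  nx <- nrow(land); ny <- ncol(land)
  lab <- matrix(NA_integer_, nx, ny)
  k <- 0L
  for (i0 in seq_len(nx)) for (j0 in seq_len(ny)) {
    if (!land[i0, j0] || !is.na(lab[i0, j0])) next
    k <- k + 1L
    stack <- list(c(i0, j0))
    lab[i0, j0] <- k
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (di in -1:1) for (dj in -1:1) {
        i <- p[1] + di; j <- p[2] + dj
        if (i >= 1 && i <= nx && j >= 1 && j <= ny &&
            land[i, j] && is.na(lab[i, j])) {
          lab[i, j] <- k
          stack[[length(stack) + 1]] <- c(i, j)
        }
      }
    }
  }
  lab
}

# brute-force minimax path value over all simple paths of a complete
# weighted graph
brute_minimax <- function(w, from, to) {
  n <- nrow(w)
  others <- setdiff(seq_len(n), c(from, to))
  best <- w[from, to]
  if (length(others)) {
    for (k in seq_along(others)) {
      combos <- utils::combn(others, k, simplify = FALSE)
      for (mid in combos) {
        for (p in all_perms(mid)) {
          nodes <- c(from, p, to)
          mx <- max(w[cbind(nodes[-length(nodes)], nodes[-1])])
          best <- min(best, mx)
        }
      }
    }
  }
  best
}

all_perms <- function(x) {
  if (length(x) <= 1) return(list(x))
  do.call(c, lapply(seq_along(x), function(i)
    lapply(all_perms(x[-i]), function(p) c(x[i], p))))
}
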