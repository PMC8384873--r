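# Corridor connectivity: per-decade suitability sets, start-to-exit
# connectivity, bisection search for the critical tolerance, the exact
# maximin (bottleneck) oracle, and windows-of-opportunity summaries.

#' Suitable node set at a tolerance threshold
#'
#' A node is suitable at threshold `p` if it is above sea level, its climate
#' value is at least `p` (inclusive), and it is not a removed barrier cell of
#' the route. Strait-exemption and Nile-delta nodes are suitable
#' unconditionally: they ignore both sea level and climate.
#'
#' @param values Numeric vector of climate values (precipitation mm/yr or
#'   aridity) on the hex-grid nodes, or a [climate_field].
#' @param grid A `hex_grid`.
#' @param land Logical land mask over nodes (see [land_mask]).
#' @param route A [route_spec] or the list returned by [route_nodes].
#' @param p Threshold (>= 0).
#' @return Logical vector over nodes, class `suitability_mask`, with
#'   attribute `p`.
#' @export
suitable_set <- function(values, grid, land, route, p) {
  if (p < 0) stop("threshold p must be non-negative")
  if (inherits(values, "climate_field")) values <- values$values
  rn <- resolve_route(route, grid)
  ok <- (land & values >= p & !rn$barrier) | rn$exempt | rn$always
  ok[is.na(ok)] <- FALSE
  structure(ok, p = p, class = "suitability_mask")
}

resolve_route <- function(route, grid) {
  if (inherits(route, "route_spec")) route_nodes(route, grid) else route
}

#' Does a connected suitable path out of Africa exist?
#'
#' True iff the start node and some exit node lie in the same connected
#' component of the suitability subgraph, where two nodes are connected if
#' their great-circle distance is at most the grid's maximum internode
#' spacing (the hex-grid adjacency). Implemented as a frontier
#' breadth-first search over the adjacency list.
#'
#' @param suitable Logical vector over nodes (see [suitable_set]).
#' @param grid A `hex_grid`.
#' @param route A [route_spec] or resolved [route_nodes] list.
#' @return Logical scalar. An unsuitable start node gives `FALSE`.
#' @export
path_exists <- function(suitable, grid, route) {
  rn <- resolve_route(route, grid)
  s <- rn$start
  if (!suitable[s]) return(FALSE)
  if (rn$is_end[s]) return(TRUE)
  n <- nrow(grid$nodes)
  visited <- logical(n)
  visited[s] <- TRUE
  frontier <- s
  adj <- grid$adj
  repeat {
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[suitable[nxt] & !visited[nxt]]
    if (!length(nxt)) return(FALSE)
    if (any(rn$is_end[nxt])) return(TRUE)
    visited[nxt] <- TRUE
    frontier <- nxt
  }
}

#' Critical tolerance by bisection
#'
#' Finds the critical threshold below which no connected path out of Africa
#' exists, by bisection on the interval `[lower, upper]`: starting from
#' `upper = 1000` mm/yr (precipitation) or `4.0` (aridity) and `lower = 0`,
#' ten iterations halve the bracket, and the critical tolerance is the
#' midpoint of the final bracket — within `(upper - lower) / 2^11` of the
#' exact maximin value (1000/2048 < 1 mm/yr for precipitation). If no path
#' exists even at `lower`, the result is flagged `blocked` with `p_crit = NA`
#' (the bisection scheme presumes connectivity at the lower bound).
#'
#' @param values Climate values on the nodes (vector or [climate_field]).
#' @param grid A `hex_grid`.
#' @param land Logical land mask.
#' @param route A [route_spec] or resolved [route_nodes] list.
#' @param variable `"precip"` or `"aridity"`; sets the default upper bound.
#' @param upper,lower Initial bracket; defaults 1000 mm/yr (precip) or 4.0
#'   (aridity), and 0.
#' @param n_iter Number of bisection iterations (default 10).
#' @return Object of class `bisection_result`: `p_hat`, `p_check` (bracket
#'   sequences of length `n_iter + 1`), `p_crit`, `blocked`, `variable`.
#' @export
critical_threshold <- function(values, grid, land, route,
                               variable = c("precip", "aridity"),
                               upper = NULL, lower = 0, n_iter = 10) {
  variable <- match.arg(variable)
  if (is.null(upper)) upper <- if (variable == "precip") 1000 else 4.0
  if (inherits(values, "climate_field")) values <- values$values
  rn <- resolve_route(route, grid)
  connected <- function(p) path_exists(suitable_set(values, grid, land, rn, p),
                                       grid, rn)
  if (!connected(lower)) {
    return(structure(list(p_hat = upper, p_check = lower, p_crit = NA_real_,
                          blocked = TRUE, variable = variable),
                     class = "bisection_result"))
  }
  p_hat <- numeric(n_iter + 1)
  p_check <- numeric(n_iter + 1)
  p_hat[1] <- upper
  p_check[1] <- lower
  for (k in seq_len(n_iter)) {
    mid <- (p_hat[k] + p_check[k]) / 2
    if (connected(mid)) {
      p_check[k + 1] <- mid
      p_hat[k + 1] <- p_hat[k]
    } else {
      p_check[k + 1] <- p_check[k]
      p_hat[k + 1] <- mid
    }
  }
  structure(list(p_hat = p_hat, p_check = p_check,
                 p_crit = (p_hat[n_iter + 1] + p_check[n_iter + 1]) / 2,
                 blocked = FALSE, variable = variable),
            class = "bisection_result")
}

#' @export
print.bisection_result <- function(x, ...) {
  if (x$blocked) cat("<bisection_result> blocked (no path at the lower bound)\n")
  else cat(sprintf("<bisection_result> %s p_crit = %.4f (bracket [%g, %g])\n",
                   x$variable, x$p_crit,
                   x$p_check[length(x$p_check)], x$p_hat[length(x$p_hat)]))
  invisible(x)
}

#' Exact corridor bottleneck (maximin path value)
#'
#' The limit of the bisection: the maximum over all start-to-exit paths of
#' the minimum climate value along the path. Computed exactly by a threshold
#' sweep — a binary search over the sorted distinct node values for the
#' largest value at which a connected path still exists. Connectivity at a
#' threshold is monotone, so the sweep is exact.
#'
#' @inheritParams critical_threshold
#' @return The bottleneck value, or `NA` (blocked sentinel) if no path
#'   exists even at threshold 0.
#' @export
bottleneck_oracle <- function(values, grid, land, route) {
  if (inherits(values, "climate_field")) values <- values$values
  rn <- resolve_route(route, grid)
  connected <- function(p) path_exists(suitable_set(values, grid, land, rn, p),
                                       grid, rn)
  if (!connected(0)) return(NA_real_)
  cand <- sort(unique(c(0, values[is.finite(values)])))
  lo <- 1L                      # connected at cand[lo]
  hi <- length(cand)
  if (connected(cand[hi])) return(cand[hi])
  while (hi - lo > 1L) {        # invariant: connected at lo, not at hi
    mid <- (lo + hi) %/% 2L
    if (connected(cand[mid])) lo <- mid else hi <- mid
  }
  cand[lo]
}

#' Windows of opportunity: fraction of connected decades per tolerance
#'
#' For each tolerance, the percentage of the 100 decades of a millennium
#' during which a connected path out of Africa existed.
#'
#' @param decadal Matrix `n_nodes x n_decades` of decadal climate values.
#' @param grid A `hex_grid`.
#' @param land Logical land mask for the millennium.
#' @param route A [route_spec] or resolved [route_nodes] list.
#' @param tolerances Numeric vector of thresholds.
#' @return Data frame with columns `tolerance` and `pct_decades` (in
#'   `[0, 100]`, non-increasing in tolerance).
#' @export
window_fractions <- function(decadal, grid, land, route, tolerances) {
  decadal <- as.matrix(decadal)
  if (any(is.na(decadal))) stop("decadal fields contain missing values")
  rn <- resolve_route(route, grid)
  pct <- vapply(tolerances, function(p) {
    ok <- vapply(seq_len(ncol(decadal)), function(d) {
      path_exists(suitable_set(decadal[, d], grid, land, rn, p), grid, rn)
    }, logical(1))
    100 * mean(ok)
  }, 0)
  data.frame(tolerance = tolerances, pct_decades = pct)
}
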