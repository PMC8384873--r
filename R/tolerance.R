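# Hunter-gatherer climate-tolerance estimation from an ethnographic
# population table.

#' Estimate the hunter-gatherer tolerance threshold
#'
#' The tolerance threshold to low precipitation (or high aridity, i.e. low
#' Koeppen index) is the level below which no hunter-gatherer population is
#' recorded: the minimum of the chosen variable over populations *not*
#' flagged as residing close to a freshwater source. Freshwater-adjacent
#' populations are not constrained by rainfall and are excluded. An optional
#' percentile generalises the minimum (percentile 0).
#'
#' @param table Data frame with columns `precip_mm_yr`, `aridity`, and
#'   logical `freshwater_adjacent` (see [make_population_table]).
#' @param variable `"precip"` or `"aridity"`.
#' @param percentile Quantile level in `[0, 1]`; 0 (default) is the minimum.
#' @return The threshold value.
#' @export
estimate_threshold <- function(table, variable = c("precip", "aridity"),
                               percentile = 0) {
  variable <- match.arg(variable)
  if (!nrow(table)) stop("empty population table")
  keep <- !table$freshwater_adjacent
  if (!any(keep)) stop("all populations are flagged as freshwater-adjacent")
  x <- switch(variable, precip = table$precip_mm_yr[keep],
              aridity = table$aridity[keep])
  unname(stats::quantile(x, probs = percentile, names = FALSE))
}

#' Histogram of populations by climate value
#'
#' Bins the population table by the chosen variable, counting
#' freshwater-adjacent (flagged) populations separately — these correspond
#' to the transparent bins of the published distribution and are not
#' considered constrained by precipitation.
#'
#' @param table Population data frame (see [estimate_threshold]).
#' @param variable `"precip"` or `"aridity"`.
#' @param bin_edges Strictly increasing numeric vector of bin edges covering
#'   all values; bins are left-closed, the last bin closed on both sides.
#' @return Data frame with columns `bin_lo`, `bin_hi`, `n`, `n_flagged`.
#' @export
population_histogram <- function(table, variable = c("precip", "aridity"),
                                 bin_edges) {
  variable <- match.arg(variable)
  if (any(diff(bin_edges) <= 0)) stop("bin edges must be strictly increasing")
  x <- switch(variable, precip = table$precip_mm_yr, aridity = table$aridity)
  if (any(x < bin_edges[1] | x > bin_edges[length(bin_edges)]))
    stop("values outside the bin range")
  b <- findInterval(x, bin_edges, rightmost.closed = TRUE)
  nb <- length(bin_edges) - 1
  flag <- table$freshwater_adjacent
  data.frame(
    bin_lo = bin_edges[-length(bin_edges)],
    bin_hi = bin_edges[-1],
    n = tabulate(b[!flag], nbins = nb),
    n_flagged = tabulate(b[flag], nbins = nb))
}
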