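# Exposure: local climate change as the standardized Euclidean distance
# (SED) between current and future climate, averaged per island.

climate_vars <- function() c("tmean", "tmax_warm", "tmin_cold",
                             "prec_ann", "prec_wet", "prec_dry")

#' Standardized Euclidean distance between two climates at one point
#'
#' Local climate change at a grid point: the sum over the six climate
#' variables of the squared current-to-future difference divided by the
#' squared seasonality standardizer,
#' \deqn{SED = \sum_{k=1}^{6} (b_k - a_k)^2 / s_k^2.}
#' The first three variables are temperature variables standardized by
#' `s_temp`; the last three are precipitation variables standardized by
#' `s_prec`. The value is the printed sum of squares (no square root),
#' symmetric in its two climate arguments and non-negative.
#'
#' @param a,b numeric length-6 current and future climate values, ordered
#'   (annual mean temperature, max temperature of the warmest month, min
#'   temperature of the coldest month, annual precipitation, precipitation
#'   of the wettest month, precipitation of the driest month).
#' @param s_temp,s_prec strictly positive seasonality standardizers.
#' @param seasonality_floor optional positive floor substituted (with a
#'   warning) for a non-positive standardizer; by default a non-positive
#'   standardizer is an error.
#' @return a single non-negative number.
#' @export
sed_point <- function(a, b, s_temp, s_prec, seasonality_floor = NULL) {
  stopifnot(length(a) == 6L, length(b) == 6L,
            all(is.finite(a)), all(is.finite(b)))
  s <- c(rep(s_temp, 3L), rep(s_prec, 3L))
  if (any(s <= 0)) {
    if (is.null(seasonality_floor))
      stopf("seasonality standardizers must be > 0 (got s_temp=%s, s_prec=%s)",
            s_temp, s_prec)
    warning("non-positive seasonality standardizer floored at ",
            seasonality_floor, call. = FALSE)
    s[s <= 0] <- seasonality_floor
  }
  sum(((b - a) / s)^2)
}

# vectorized SED over grid rows (one scenario block); returns one value/row
sed_rows <- function(grid) {
  v <- climate_vars()
  a <- as.matrix(grid[paste0("cur_", v)])
  b <- as.matrix(grid[paste0("fut_", v)])
  s <- cbind(grid$s_temp, grid$s_temp, grid$s_temp,
             grid$s_prec, grid$s_prec, grid$s_prec)
  if (any(s <= 0)) stopf("non-positive seasonality standardizer in grid")
  rowSums(((b - a) / s)^2)
}

# grid points belonging to island_id plus, for buffer_km > 0, every other
# grid point whose minimum planar distance to the island's own points is
# <= buffer_km
buffer_members <- function(grid, island_id, buffer_km) {
  own <- grid$island_id == island_id
  if (!any(own)) stopf("unknown island_id '%s' in climate grid", island_id)
  if (buffer_km <= 0) return(own)
  px <- grid$x[own]; py <- grid$y[own]
  d2min <- rep(Inf, nrow(grid))
  for (j in seq_along(px)) {
    d2 <- (grid$x - px[j])^2 + (grid$y - py[j])^2
    d2min <- pmin(d2min, d2)
  }
  own | d2min <= buffer_km^2
}

#' Island-level exposure for one island
#'
#' Mean per-grid-point SED over the island's own points (`buffer_km = 0`)
#' or over its points plus all grid points within `buffer_km` planar
#' distance of the island's point set (points of neighbouring islands a
#' disperser might reach).
#'
#' @param grid a climate grid (see [generate_climate()] for the column
#'   contract); rows of a single future-scenario block are used.
#' @param island_id island to evaluate.
#' @param buffer_km buffer radius in km; 0, 100 and 500 are the
#'   conventional choices.
#' @param scenario_label which future block to use; default the first
#'   present.
#' @return a one-row data.frame: `island_id`, `buffer_km`, `scenario`,
#'   `mean_sed`, `n_points_used`.
#' @export
island_exposure <- function(grid, island_id, buffer_km = 0,
                            scenario_label = NULL) {
  scenario_label <- scenario_label %||% grid$scenario[1]
  g <- grid[grid$scenario == scenario_label, , drop = FALSE]
  if (nrow(g) == 0L) stopf("no grid rows for scenario '%s'", scenario_label)
  keep <- buffer_members(g, island_id, buffer_km)
  sed <- sed_rows(g[keep, , drop = FALSE])
  data.frame(island_id = island_id, buffer_km = buffer_km,
             scenario = scenario_label, mean_sed = mean(sed),
             n_points_used = sum(keep), stringsAsFactors = FALSE)
}

#' Exposure for all islands across all future scenario blocks
#'
#' Computes per-island mean SED separately for every future block (e.g.
#' each GCM), then averages across blocks — the ensemble-mean exposure.
#'
#' @param grid a climate grid with one or more scenario blocks.
#' @param buffer_km buffer radius passed to [island_exposure()].
#' @return a list: `ensemble` (data.frame `island_id`, `buffer_km`,
#'   `mean_sed`, `n_points_used`) and `per_scenario` (the per-block rows,
#'   retained for inspection).
#' @export
multi_scenario_exposure <- function(grid, buffer_km = 0) {
  labels <- unique(grid$scenario)
  if (length(labels) < 1L) stopf("no future scenario block present")
  islands <- unique(grid$island_id)
  key <- function(g) paste(g$island_id, g$point_id)
  ref <- sort(key(grid[grid$scenario == labels[1], ]))
  for (lb in labels[-1])
    if (!identical(sort(key(grid[grid$scenario == lb, ])), ref))
      stopf("scenario block '%s' has mismatched point keys", lb)
  per <- do.call(rbind, lapply(labels, function(lb)
    do.call(rbind, lapply(islands, island_exposure, grid = grid,
                          buffer_km = buffer_km, scenario_label = lb))))
  ens <- stats::aggregate(mean_sed ~ island_id, per, mean)
  npts <- per$n_points_used[match(ens$island_id, per$island_id)]
  ens <- data.frame(island_id = ens$island_id, buffer_km = buffer_km,
                    mean_sed = ens$mean_sed, n_points_used = npts,
                    stringsAsFactors = FALSE)
  ens <- ens[match(islands, ens$island_id), ]
  rownames(ens) <- NULL
  list(ensemble = ens, per_scenario = per)
}
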