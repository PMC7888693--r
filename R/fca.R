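#' Demand and supply point sets
#'
#' Light validating constructors for the two point layers every floating
#' catchment area method consumes: population locations with inhabitant
#' counts, and service sites with capacities (e.g. number of practitioners
#' at a practice).
#'
#' @param df data.frame with columns `id`, `x`, `y` and `pop` (demand,
#'   counts >= 0) or `capacity` (supply, > 0).
#' @return The validated data.frame, classed `demand_set` / `supply_set`.
#' @name point_sets
NULL

#' @rdname point_sets
#' @export
demand_set <- function(df) {
  if (!all(c("id", "x", "y", "pop") %in% names(df)))
    stop("demand needs columns id, x, y, pop")
  if (anyDuplicated(df$id)) stop("duplicate demand ids")
  if (any(!is.finite(df$pop)) || any(df$pop < 0))
    stop("population counts must be finite and non-negative")
  df <- as.data.frame(df)[c("id", "x", "y", "pop")]
  rownames(df) <- NULL
  class(df) <- c("demand_set", "data.frame")
  df
}

#' @rdname point_sets
#' @export
supply_set <- function(df) {
  if (!all(c("id", "x", "y", "capacity") %in% names(df)))
    stop("supply needs columns id, x, y, capacity")
  if (anyDuplicated(df$id)) stop("duplicate supply ids")
  if (any(!is.finite(df$capacity)) || any(df$capacity <= 0))
    stop("capacities must be finite and strictly positive; drop or aggregate zero-capacity sites at load time")
  df <- as.data.frame(df)[c("id", "x", "y", "capacity")]
  rownames(df) <- NULL
  class(df) <- c("supply_set", "data.frame")
  df
}

check_ids <- function(od, supply, demand) {
  bad_s <- setdiff(unique(od$supply_id), supply$id)
  if (length(bad_s))
    stop("OD matrix references unknown supply ids: ",
         paste(utils::head(bad_s, 5), collapse = ", "))
  bad_d <- setdiff(unique(od$demand_id), demand$id)
  if (length(bad_d))
    stop("OD matrix references unknown demand ids: ",
         paste(utils::head(bad_d, 5), collapse = ", "))
  invisible(TRUE)
}

#' Huff interaction probabilities over a sparse OD structure
#'
#' First step of the MH3SFCA method. Every reachable pair (i, j) receives a
#' distance-decay weight \eqn{W_{ij}} from `params`, and the probability
#' that population i interacts with site j is the capacity-weighted share
#' \deqn{Huff_{ij} = S_j W_{ij} / \sum_k S_k W_{ik}}
#' over all sites k within i's catchment. Rows of each demand location sum
#' to one, which is what keeps total demand constant in the later steps.
#'
#' @param od An [od_matrix()] (already thresholded at `d_max`).
#' @param supply A [supply_set()] covering every supply id in `od`.
#' @param params A [decay_params()]; its `d_max` must be >= the matrix's.
#' @return data.frame with columns `demand_id`, `supply_id`, `minutes`,
#'   `weight`, `huff`; `params` attached as an attribute.
#' @export
build_interactions <- function(od, supply, params) {
  stopifnot(inherits(od, "od_matrix"), inherits(params, "decay_params"))
  supply <- supply_set(supply)
  bad <- setdiff(unique(od$supply_id), supply$id)
  if (length(bad))
    stop("OD matrix references unknown supply ids: ",
         paste(utils::head(bad, 5), collapse = ", "))
  tab <- as.data.frame(od)
  tab$weight <- weight_for(tab$minutes, params)
  s_j <- supply$capacity[match(tab$supply_id, supply$id)]
  sw <- s_j * tab$weight
  denom <- rowsum(sw, group = tab$demand_id, reorder = FALSE)
  tab$huff <- sw / denom[match(tab$demand_id, rownames(denom)), 1L]
  attr(tab, "params") <- params
  tab
}

#' Huff-allocated supply-demand ratios
#'
#' Second step: each site's capacity divided by the demand actually
#' allocated to it, \eqn{R_j = S_j / \sum_i Huff_{ij} D_i} over the
#' populations within its catchment. Units are providers per person. Sites
#' with zero allocated demand (no reachable population, or only empty cells)
#' get \eqn{R_j = 0} with a warning rather than an error, so isolated sites
#' do not abort a regional run.
#'
#' @param interactions Output of [build_interactions()].
#' @param supply The same [supply_set()] the interactions were built with.
#' @param demand A [demand_set()] covering every demand id in `interactions`.
#' @return Named numeric vector of ratios, one per supply site (in `supply`
#'   order).
#' @export
supply_demand_ratio <- function(interactions, supply, demand) {
  supply <- supply_set(supply); demand <- demand_set(demand)
  check_ids(interactions, supply, demand)
  d_i <- demand$pop[match(interactions$demand_id, demand$id)]
  hd <- rowsum(interactions$huff * d_i, group = interactions$supply_id, reorder = FALSE)
  denom <- stats::setNames(rep(0, nrow(supply)), supply$id)
  denom[rownames(hd)] <- hd[, 1L]
  r <- ifelse(denom > 0, supply$capacity / ifelse(denom > 0, denom, 1), 0)
  undemanded <- sum(denom == 0)
  if (undemanded > 0)
    warning(sprintf("%d supply site(s) with no allocated demand; their ratio is set to 0",
                    undemanded))
  stats::setNames(r, supply$id)
}

#' Accessibility index
#'
#' Third step: the opportunities per person available to each population
#' location, \eqn{A_i = \sum_j Huff_{ij} R_j W_{ij}} over the sites within
#' its catchment. Locations with no reachable supply get \eqn{A_i = 0}.
#'
#' @param interactions Output of [build_interactions()].
#' @param ratios Ratios from [supply_demand_ratio()] (named by supply id).
#' @param demand A [demand_set()]; every demand location gets an index.
#' @return Named numeric vector of indices, one per demand location.
#' @export
accessibility_index <- function(interactions, ratios, demand) {
  demand <- demand_set(demand)
  r_j <- ratios[match(interactions$supply_id, names(ratios))]
  contrib <- rowsum(interactions$huff * r_j * interactions$weight,
                    group = interactions$demand_id, reorder = FALSE)
  a <- stats::setNames(rep(0, nrow(demand)), demand$id)
  a[rownames(contrib)] <- contrib[, 1L]
  a
}

new_fca_result <- function(method, demand, a, ratios, meta) {
  res_d <- as.data.frame(demand)
  res_d$A <- as.numeric(a[match(as.character(res_d$id), names(a))])
  structure(list(
    demand = res_d,
    ratios = data.frame(supply_id = names(ratios), R = as.numeric(ratios)),
    method = method,
    meta = meta
  ), class = "fca_result")
}

#' Modified Huff-model three-step floating catchment area method
#'
#' Composes the three steps — Huff interaction probabilities
#' ([build_interactions()]), Huff-allocated supply-demand ratios
#' ([supply_demand_ratio()]) and distance-weighted accessibility indices
#' ([accessibility_index()]) — into one run. Demand is allocated across
#' alternatives so the total allocated demand equals the total covered
#' population (no demand over-counting), and the final distance weighting
#' penalises sub-optimally placed supply, so the population-weighted index
#' sum never exceeds total capacity.
#'
#' @param od An [od_matrix()] of in-catchment travel times.
#' @param supply A [supply_set()].
#' @param demand A [demand_set()].
#' @param params A [decay_params()].
#' @param keep_interactions Keep the per-pair table in the result (can be
#'   large). Default `FALSE`.
#' @return An object of class `fca_result`: per-location indices `A`,
#'   per-site ratios `R`, and run metadata.
#' @examples
#' dem <- demand_set(data.frame(id = 1:2, x = c(0, 1), y = 0, pop = c(100, 50)))
#' sup <- supply_set(data.frame(id = "s1", x = 0, y = 0, capacity = 2))
#' od  <- od_matrix(data.frame(demand_id = c(1, 2), supply_id = "s1",
#'                             minutes = c(0, 10)), d_max = 30)
#' res <- mh3sfca(od, sup, dem, decay_params(30, 0.01))
#' summary(res)
#' @export
mh3sfca <- function(od, supply, demand, params = decay_params(),
                    keep_interactions = FALSE) {
  supply <- supply_set(supply); demand <- demand_set(demand)
  check_ids(od, supply, demand)
  inter <- build_interactions(od, supply, params)
  r <- supply_demand_ratio(inter, supply, demand)
  a <- accessibility_index(inter, r, demand)
  covered <- unique(as.character(inter$demand_id))
  meta <- list(method = "mh3sfca", d_max = params$d_max, beta = params$beta,
               w_min = params$w_min, mode = params$mode,
               n_zones = if (params$mode == "subzones") params$n_zones else NA_integer_,
               n_pairs = nrow(inter),
               n_demand = nrow(demand), n_supply = nrow(supply),
               n_uncovered_demand = nrow(demand) - length(covered),
               n_undemanded_supply = sum(r == 0))
  res <- new_fca_result("mh3sfca", demand, a, r, meta)
  if (keep_interactions) res$interactions <- inter
  res
}

#' @export
print.fca_result <- function(x, ...) {
  cat(sprintf("Floating catchment area result (%s)\n", toupper(x$method)))
  cat(sprintf("  %d demand locations, %d supply sites, %d in-catchment pairs\n",
              x$meta$n_demand, x$meta$n_supply, x$meta$n_pairs))
  cat(sprintf("  d_max = %g min", x$meta$d_max))
  if (!is.null(x$meta$beta) && is.finite(x$meta$beta))
    cat(sprintf(", beta = %g min^2, mode = %s", x$meta$beta, x$meta$mode))
  cat("\n")
  s <- summary(x)
  cat(sprintf("  A: min %s, max %s, pop-weighted mean %s (%d with zero access)\n",
              format_trunc8(s$min), format_trunc8(s$max),
              format_trunc8(s$weighted_mean), s$n_zero_access))
  invisible(x)
}

#' Summarise an accessibility result
#'
#' Minimum, maximum, population-weighted mean (\eqn{\sum A_i D_i / \sum
#' D_i}), unweighted mean and count of zero-access locations. The print
#' method shows indices truncated (not rounded) to eight decimals, the
#' convention for mapping these small providers-per-person values; full
#' precision is retained in the returned object and in any CSV output.
#'
#' @param object An `fca_result`.
#' @param ... Unused.
#' @return A list of class `summary.fca_result`.
#' @export
summary.fca_result <- function(object, ...) {
  a <- object$demand$A
  d <- object$demand$pop
  if (length(a) == 0L) stop("empty result")
  wmean <- if (sum(d) > 0) sum(a * d) / sum(d) else NA_real_
  structure(list(method = object$method,
                 n = length(a),
                 min = min(a), max = max(a),
                 weighted_mean = wmean, mean = mean(a),
                 n_zero_access = sum(a == 0)),
            class = "summary.fca_result")
}

#' @export
print.summary.fca_result <- function(x, ...) {
  cat(sprintf("Accessibility summary (%s), %d locations\n", toupper(x$method), x$n))
  cat(sprintf("  min                  : %s\n", format_trunc8(x$min)))
  cat(sprintf("  max                  : %s\n", format_trunc8(x$max)))
  cat(sprintf("  pop-weighted mean    : %s\n", format_trunc8(x$weighted_mean)))
  cat(sprintf("  unweighted mean      : %s\n", format_trunc8(x$mean)))
  cat(sprintf("  zero-access locations: %d\n", x$n_zero_access))
  invisible(x)
}

#' @export
as.data.frame.fca_result <- function(x, ...) x$demand

#' Plot an accessibility surface
#'
#' Scatter of demand locations coloured by quantile class of the index
#' (blue = low, red = high), with supply shown if ratios carry coordinates.
#'
#' @param x An `fca_result`.
#' @param k Number of quantile classes. Default 5.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.fca_result <- function(x, k = 5, ...) {
  cls <- quantile_classify(x$demand$A, k)
  pal <- grDevices::colorRampPalette(c("darkblue", "lightblue", "yellow",
                                       "orange", "darkred"))(k)
  graphics::plot(x$demand$x, x$demand$y, col = pal[cls], pch = 15, cex = 0.6,
                 xlab = "x (m)", ylab = "y (m)", asp = 1,
                 main = sprintf("Accessibility index (%s), %d quantile classes",
                                toupper(x$method), k), ...)
  invisible(x)
}
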