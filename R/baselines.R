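# Reference implementations of the classic floating catchment area lineage,
# for comparison runs against the Huff-allocated method. Formulas follow the
# originating literature: Luo & Wang (2003) for 2SFCA, Luo & Qi (2009) for
# E2SFCA, Wan et al. (2012) for 3SFCA, Delamater (2013) for M2SFCA.

ratio_with_degenerate <- function(capacity, denom, ids) {
  r <- ifelse(denom > 0, capacity / pmax(denom, .Machine$double.xmin), 0)
  if (any(denom == 0))
    warning(sprintf("%d supply site(s) with no in-catchment demand; their ratio is set to 0",
                    sum(denom == 0)))
  stats::setNames(r, ids)
}

grouped_sum <- function(values, group, all_ids) {
  s <- rowsum(values, group = group, reorder = FALSE)
  out <- stats::setNames(rep(0, length(all_ids)), all_ids)
  out[rownames(s)] <- s[, 1L]
  out
}

baseline_meta <- function(method, od, supply, demand, r, a, params = NULL) {
  list(method = method,
       d_max = attr(od, "d_max"),
       beta = if (is.null(params)) NA_real_ else params$beta,
       w_min = if (is.null(params)) NA_real_ else params$w_min,
       mode = if (is.null(params)) "binary" else params$mode,
       n_zones = if (!is.null(params) && params$mode == "subzones") params$n_zones else NA_integer_,
       n_pairs = nrow(od),
       n_demand = nrow(demand), n_supply = nrow(supply),
       n_uncovered_demand = sum(a == 0),
       n_undemanded_supply = sum(r == 0))
}

#' Two-step floating catchment area method (2SFCA)
#'
#' The classic binary-catchment method: every population within `d_max` of a
#' site contributes its full demand to that site's ratio, and every site
#' within `d_max` of a population contributes its full ratio to the index:
#' \deqn{R_j = S_j / \sum_{i: d_{ij} \le d_{max}} D_i, \qquad
#'       A_i = \sum_{j: d_{ij} \le d_{max}} R_j.}
#' Because each population is counted in full at every reachable site, the
#' method over-states demand wherever catchments overlap.
#'
#' @param od An [od_matrix()].
#' @param supply A [supply_set()].
#' @param demand A [demand_set()].
#' @return An `fca_result`.
#' @export
fca_2sfca <- function(od, supply, demand) {
  supply <- supply_set(supply); demand <- demand_set(demand)
  check_ids(od, supply, demand)
  d_i <- demand$pop[match(od$demand_id, demand$id)]
  denom <- grouped_sum(d_i, od$supply_id, supply$id)
  r <- ratio_with_degenerate(supply$capacity, denom, supply$id)
  a <- grouped_sum(r[match(od$supply_id, names(r))], od$demand_id, demand$id)
  new_fca_result("2sfca", demand, a, r,
                 baseline_meta("2sfca", od, supply, demand, r, a))
}

#' Enhanced two-step floating catchment area method (E2SFCA)
#'
#' 2SFCA with discrete distance decay: the catchment is cut into travel-time
#' bands ([subzone_scheme()]) and each pair is weighted by its band's
#' Gaussian weight \eqn{W_r}:
#' \deqn{R_j = S_j / \sum_i D_i W_r, \qquad A_i = \sum_j R_j W_r.}
#'
#' @inheritParams fca_2sfca
#' @param params A [decay_params()] with `mode = "subzones"`.
#' @return An `fca_result`.
#' @export
fca_e2sfca <- function(od, supply, demand, params) {
  stopifnot(inherits(params, "decay_params"))
  if (params$mode != "subzones")
    stop("E2SFCA requires decay_params(mode = \"subzones\")")
  supply <- supply_set(supply); demand <- demand_set(demand)
  check_ids(od, supply, demand)
  w <- weight_for(od$minutes, params)
  d_i <- demand$pop[match(od$demand_id, demand$id)]
  denom <- grouped_sum(d_i * w, od$supply_id, supply$id)
  r <- ratio_with_degenerate(supply$capacity, denom, supply$id)
  a <- grouped_sum(r[match(od$supply_id, names(r))] * w, od$demand_id, demand$id)
  new_fca_result("e2sfca", demand, a, r,
                 baseline_meta("e2sfca", od, supply, demand, r, a, params))
}

#' Three-step floating catchment area method (3SFCA)
#'
#' Adds competition between sites through a travel-time-only selection
#' weight \eqn{G_{ij} = W_{ij} / \sum_k W_{ik}} (capacity does not enter the
#' allocation, unlike the Huff scheme):
#' \deqn{R_j = S_j / \sum_i G_{ij} D_i W_{ij}, \qquad
#'       A_i = \sum_j G_{ij} R_j W_{ij}.}
#'
#' @inheritParams fca_2sfca
#' @param params A [decay_params()].
#' @return An `fca_result`.
#' @export
fca_3sfca <- function(od, supply, demand, params) {
  stopifnot(inherits(params, "decay_params"))
  supply <- supply_set(supply); demand <- demand_set(demand)
  check_ids(od, supply, demand)
  w <- weight_for(od$minutes, params)
  wsum <- rowsum(w, group = od$demand_id, reorder = FALSE)
  g <- w / wsum[match(od$demand_id, rownames(wsum)), 1L]
  d_i <- demand$pop[match(od$demand_id, demand$id)]
  denom <- grouped_sum(g * d_i * w, od$supply_id, supply$id)
  r <- ratio_with_degenerate(supply$capacity, denom, supply$id)
  a <- grouped_sum(g * r[match(od$supply_id, names(r))] * w, od$demand_id, demand$id)
  new_fca_result("3sfca", demand, a, r,
                 baseline_meta("3sfca", od, supply, demand, r, a, params))
}

#' Modified two-step floating catchment area method (M2SFCA)
#'
#' Distance-weights both the demand side of the ratio and, squared, the
#' index, so a sub-optimal spatial configuration of sites lowers the indices
#' even when supply and demand totals are unchanged:
#' \deqn{A_i = \sum_j \frac{S_j W_{ij}^2}{\sum_k D_k W_{kj}}.}
#'
#' @inheritParams fca_2sfca
#' @param params A [decay_params()].
#' @return An `fca_result`. The stored ratio is the demand-weighted
#'   \eqn{S_j / \sum_k D_k W_{kj}}.
#' @export
fca_m2sfca <- function(od, supply, demand, params) {
  stopifnot(inherits(params, "decay_params"))
  supply <- supply_set(supply); demand <- demand_set(demand)
  check_ids(od, supply, demand)
  w <- weight_for(od$minutes, params)
  d_i <- demand$pop[match(od$demand_id, demand$id)]
  denom <- grouped_sum(d_i * w, od$supply_id, supply$id)
  r <- ratio_with_degenerate(supply$capacity, denom, supply$id)
  a <- grouped_sum(r[match(od$supply_id, names(r))] * w^2, od$demand_id, demand$id)
  new_fca_result("m2sfca", demand, a, r,
                 baseline_meta("m2sfca", od, supply, demand, r, a, params))
}

#' Run any floating catchment area method by name
#'
#' Uniform front end over [mh3sfca()] and the baselines, with an identical
#' input/output contract so results are directly comparable.
#'
#' @param method One of `"mh3sfca"`, `"2sfca"`, `"e2sfca"`, `"3sfca"`,
#'   `"m2sfca"`.
#' @inheritParams mh3sfca
#' @return An `fca_result`.
#' @export
fca_access <- function(method = c("mh3sfca", "2sfca", "e2sfca", "3sfca", "m2sfca"),
                       od, supply, demand, params = decay_params()) {
  method <- match.arg(method)
  switch(method,
         mh3sfca = mh3sfca(od, supply, demand, params),
         `2sfca` = fca_2sfca(od, supply, demand),
         e2sfca = fca_e2sfca(od, supply, demand, params),
         `3sfca` = fca_3sfca(od, supply, demand, params),
         m2sfca = fca_m2sfca(od, supply, demand, params))
}
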