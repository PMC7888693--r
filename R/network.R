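#' Directed road network
#'
#' Builds a validated road-network object from a node table and a directed
#' edge table. Edge traversal cost in minutes is derived from length and
#' speed limit; one-way streets are represented by the absence of the
#' reverse edge. Coordinates are planar metres (projected) — no coordinate
#' transformation is performed.
#'
#' @param nodes data.frame with columns `node_id`, `x`, `y` (metres).
#' @param edges data.frame with columns `from_node`, `to_node`,
#'   `length_m` (> 0) and `speed_kmh` (> 0). Each row is one directed edge.
#' @return An object of class `road_network`: a list with elements `nodes`
#'   and `edges`, the latter gaining a `minutes` column.
#' @export
road_network <- function(nodes, edges) {
  need_n <- c("node_id", "x", "y")
  need_e <- c("from_node", "to_node", "length_m", "speed_kmh")
  if (!all(need_n %in% names(nodes)))
    stop("`nodes` must have columns node_id, x, y")
  if (!all(need_e %in% names(edges)))
    stop("`edges` must have columns from_node, to_node, length_m, speed_kmh")
  if (anyDuplicated(nodes$node_id))
    stop("duplicate node ids")
  missing_ep <- setdiff(c(edges$from_node, edges$to_node), nodes$node_id)
  if (length(missing_ep))
    stop("edge endpoints not in node table: ", paste(utils::head(missing_ep, 5), collapse = ", "))
  if (any(edges$length_m <= 0) || any(edges$speed_kmh <= 0))
    stop("edge lengths and speeds must be strictly positive")
  edges$minutes <- edge_travel_time(edges$length_m, edges$speed_kmh)
  structure(list(nodes = nodes[need_n], edges = edges[c(need_e, "minutes")]),
            class = "road_network")
}

#' @export
print.road_network <- function(x, ...) {
  cat(sprintf("Road network: %d nodes, %d directed edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Edge travel time from length and speed limit
#'
#' `minutes = (length_m / 1000) / speed_kmh * 60`, i.e. `length_m * 0.06 /
#' speed_kmh`.
#'
#' @param length_m Edge length in metres (> 0). Vectorised.
#' @param speed_kmh Speed limit in km/h (> 0). Vectorised.
#' @return Travel time in minutes.
#' @export
edge_travel_time <- function(length_m, speed_kmh) {
  if (any(!is.finite(length_m)) || any(length_m <= 0))
    stop("`length_m` must be finite and positive")
  if (any(!is.finite(speed_kmh)) || any(speed_kmh <= 0))
    stop("`speed_kmh` must be finite and positive")
  length_m * 0.06 / speed_kmh
}

#' Snap points to their nearest network node
#'
#' Each point maps to the nearest node by Euclidean distance; ties break
#' deterministically to the smallest node id.
#'
#' @param points data.frame with columns `id`, `x`, `y`.
#' @param network A [road_network()].
#' @return Named vector of node ids, names are the point ids.
#' @export
snap_points <- function(points, network) {
  stopifnot(inherits(network, "road_network"))
  if (nrow(network$nodes) == 0L) stop("empty network")
  nd <- network$nodes[order(network$nodes$node_id), ]
  nx <- nd$x; ny <- nd$y
  idx <- vapply(seq_len(nrow(points)), function(r) {
    which.min((nx - points$x[r])^2 + (ny - points$y[r])^2)  # first min = smallest id
  }, integer(1))
  stats::setNames(nd$node_id[idx], points$id)
}

#' Sparse origin-destination travel-time matrix
#'
#' Long-format table of shortest-path travel times between demand and supply
#' locations, pruned at the catchment threshold: a row is stored iff the
#' travel time is `<= d_max` (inclusive). Out-of-catchment and unreachable
#' pairs are simply absent.
#'
#' @param entries data.frame with columns `demand_id`, `supply_id`,
#'   `minutes` (>= 0; zero is allowed for co-located points).
#' @param d_max Catchment threshold in minutes (> 0).
#' @return An object of classes `od_matrix` and `data.frame` with attribute
#'   `d_max`.
#' @export
od_matrix <- function(entries, d_max) {
  need <- c("demand_id", "supply_id", "minutes")
  if (!all(need %in% names(entries)))
    stop("`entries` must have columns demand_id, supply_id, minutes")
  if (!is.numeric(d_max) || length(d_max) != 1L || d_max <= 0)
    stop("`d_max` must be a single positive number")
  entries <- as.data.frame(entries)[need]
  if (any(!is.finite(entries$minutes)) || any(entries$minutes < 0))
    stop("travel times must be finite and non-negative")
  if (any(entries$minutes > d_max))
    stop("entries contain travel times beyond d_max")
  if (anyDuplicated(paste(entries$demand_id, entries$supply_id, sep = "\r")))
    stop("duplicate (demand_id, supply_id) pairs")
  rownames(entries) <- NULL
  structure(entries, d_max = d_max, class = c("od_matrix", "data.frame"))
}

igraph_from_network <- function(network) {
  verts <- data.frame(name = as.character(network$nodes$node_id))
  ed <- data.frame(from = as.character(network$edges$from_node),
                   to = as.character(network$edges$to_node),
                   weight = network$edges$minutes)
  igraph::graph_from_data_frame(ed, directed = TRUE, vertices = verts)
}

#' Thresholded shortest-path OD travel-time matrix on a road network
#'
#' Computes, for every origin, the shortest-path travel time (Dijkstra on the
#' directed edge costs, origin to destination, respecting one-way streets) to
#' every destination, and keeps the pairs within the catchment threshold.
#' Travel direction is population to supply throughout.
#'
#' @param network A [road_network()].
#' @param origins Named vector of node ids (names = demand ids), e.g. from
#'   [snap_points()]. An unnamed vector uses the node ids as demand ids.
#' @param destinations Named vector of node ids (names = supply ids).
#' @param d_max Catchment threshold in minutes (> 0).
#' @return An [od_matrix()].
#' @export
od_cost_matrix <- function(network, origins, destinations, d_max) {
  stopifnot(inherits(network, "road_network"))
  if (!is.numeric(d_max) || length(d_max) != 1L || d_max <= 0)
    stop("`d_max` must be a single positive number")
  if (is.null(names(origins))) names(origins) <- as.character(origins)
  if (is.null(names(destinations))) names(destinations) <- as.character(destinations)
  unknown <- setdiff(c(origins, destinations), network$nodes$node_id)
  if (length(unknown))
    stop("unknown node ids: ", paste(utils::head(unknown, 5), collapse = ", "))
  g <- igraph_from_network(network)
  o_nodes <- unique(as.character(origins))
  d_nodes <- unique(as.character(destinations))
  dm <- igraph::distances(g, v = o_nodes, to = d_nodes, mode = "out",
                          weights = igraph::E(g)$weight, algorithm = "dijkstra")
  # expand node-level times to point-level pairs, then prune at the threshold
  t_pt <- dm[match(as.character(origins), o_nodes),
             match(as.character(destinations), d_nodes), drop = FALSE]
  keep <- which(is.finite(t_pt) & t_pt <= d_max, arr.ind = TRUE)
  od_matrix(data.frame(demand_id = names(origins)[keep[, 1]],
                       supply_id = names(destinations)[keep[, 2]],
                       minutes = t_pt[keep]),
            d_max)
}

#' Straight-line OD travel-time matrix
#'
#' Euclidean fallback when no road network is available: travel time is the
#' straight-line distance at a constant speed, thresholded at `d_max`.
#'
#' @param demand data.frame with columns `id`, `x`, `y`.
#' @param supply data.frame with columns `id`, `x`, `y`.
#' @param speed_kmh Constant travel speed (> 0).
#' @param d_max Catchment threshold in minutes (> 0).
#' @return An [od_matrix()].
#' @export
od_matrix_euclidean <- function(demand, supply, speed_kmh, d_max) {
  if (!is.numeric(speed_kmh) || length(speed_kmh) != 1L || speed_kmh <= 0)
    stop("`speed_kmh` must be a single positive number")
  dx <- outer(demand$x, supply$x, "-")
  dy <- outer(demand$y, supply$y, "-")
  t_min <- sqrt(dx^2 + dy^2) * 0.06 / speed_kmh
  keep <- which(t_min <= d_max, arr.ind = TRUE)
  od_matrix(data.frame(demand_id = demand$id[keep[, 1]],
                       supply_id = supply$id[keep[, 2]],
                       minutes = t_min[keep]),
            d_max)
}
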