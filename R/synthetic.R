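# Seeded generators for synthetic study regions: a hectare population grid
# with an urban/rural density gradient, clustered service sites with small
# integer capacities, and a lattice car network with heterogeneous speed
# limits and one-way streets. Everything is deterministic under the seed.

#' Configuration for a synthetic study region
#'
#' The population surface is a sum of exponential density peaks (one peak =
#' a monocentric city) over a uniform rural floor, realised as independent
#' Poisson counts on a square grid of `cell_size`-metre cells — the
#' structure of a national census hectare grid. Supply sites mix
#' population-proportional and uniform placement; the road network is a
#' lattice with randomly assigned speed classes and a fraction of one-way
#' edges.
#'
#' @param seed Integer seed; fixed seed gives identical output.
#' @param extent Width and height of the region in metres.
#' @param cell_size Grid cell edge in metres (default 100, a hectare cell).
#' @param centers data.frame with columns `x`, `y`, `peak` (mean inhabitants
#'   per cell at the peak) and `decay_m` (exponential decay length in
#'   metres). Default: one city centre in the middle of the extent with a
#'   peak of 50 inhabitants per hectare cell and a 2 km decay length.
#' @param pop_floor Uniform rural mean inhabitants per cell (default 0.2;
#'   most rural cells are empty, as forests and fields are).
#' @param n_supply Number of service sites (default 25).
#' @param clustering Share of sites placed population-proportionally rather
#'   than uniformly, in `[0, 1]` (default 0.8).
#' @param capacity_range Integer range for site capacities (default 1 to 5
#'   practitioners per practice).
#' @param lattice_spacing Road-lattice spacing in metres (default 500).
#' @param speed_classes Speed limits sampled per street (default
#'   30/50/80/100 km/h).
#' @param oneway_frac Fraction of streets made one-way (default 0.1).
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(seed = 1L,
                            extent = c(10000, 10000),
                            cell_size = 100,
                            centers = NULL,
                            pop_floor = 0.2,
                            n_supply = 25L,
                            clustering = 0.8,
                            capacity_range = c(1L, 5L),
                            lattice_spacing = 500,
                            speed_classes = c(30, 50, 80, 100),
                            oneway_frac = 0.1) {
  if (any(extent <= 0)) stop("extent must be positive")
  if (cell_size <= 0) stop("cell_size must be positive")
  if (clustering < 0 || clustering > 1) stop("clustering must be in [0, 1]")
  if (oneway_frac < 0 || oneway_frac > 1) stop("oneway_frac must be in [0, 1]")
  if (pop_floor < 0) stop("pop_floor must be non-negative")
  if (n_supply < 1) stop("n_supply must be at least 1")
  if (capacity_range[1] < 1 || capacity_range[2] < capacity_range[1])
    stop("capacity_range must be an increasing range of positive integers")
  if (is.null(centers))
    centers <- data.frame(x = extent[1] / 2, y = extent[2] / 2,
                          peak = 50, decay_m = 2000)
  structure(list(seed = as.integer(seed), extent = extent,
                 cell_size = cell_size, centers = centers,
                 pop_floor = pop_floor, n_supply = as.integer(n_supply),
                 clustering = clustering,
                 capacity_range = as.integer(capacity_range),
                 lattice_spacing = lattice_spacing,
                 speed_classes = speed_classes, oneway_frac = oneway_frac),
            class = "scenario_config")
}

#' Preset study-region configurations
#'
#' `"monocentric"` is the default single-city region; `"two-town"` places
#' two density peaks of different size; `"uniform"` has no peak, only a
#' denser uniform floor.
#'
#' @param preset One of `"monocentric"`, `"two-town"`, `"uniform"`.
#' @param seed Integer seed.
#' @param ... Overrides passed to [scenario_config()].
#' @return A `scenario_config`.
#' @export
scenario_preset <- function(preset = c("monocentric", "two-town", "uniform"),
                            seed = 1L, ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    monocentric = list(),
    # two towns must sit further apart than the 30-minute car-travel scale,
    # or their catchments merge into one; hence the larger extent
    `two-town` = list(extent = c(30000, 30000),
                      centers = data.frame(
                        x = c(7500, 22500), y = c(7500, 22500),
                        peak = c(50, 35), decay_m = c(2000, 2000)),
                      n_supply = 40L, lattice_spacing = 1000),
    uniform = list(centers = data.frame(x = 0, y = 0, peak = 0, decay_m = 1),
                   pop_floor = 2, clustering = 0)
  )
  do.call(scenario_config, c(list(seed = seed), base, list(...)))
}

# Expected (Poisson mean) inhabitants for cells centred at (x, y).
density_mean <- function(x, y, config) {
  lambda <- rep(config$pop_floor, length(x))
  for (ci in seq_len(nrow(config$centers))) {
    cc <- config$centers[ci, ]
    r <- sqrt((x - cc$x)^2 + (y - cc$y)^2)
    lambda <- lambda + cc$peak * exp(-r / cc$decay_m)
  }
  lambda
}

#' Generate a synthetic hectare population grid
#'
#' Cell centroids with Poisson inhabitant counts whose means follow the
#' configured density surface; empty cells are dropped, so the returned
#' demand set is sparse like a real census grid with unpopulated land.
#'
#' @param config A [scenario_config()].
#' @return A [demand_set()] with ids `d1, d2, ...` in row-major cell order.
#' @export
make_population_grid <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  cs <- config$cell_size
  nx <- max(1L, floor(config$extent[1] / cs))
  ny <- max(1L, floor(config$extent[2] / cs))
  gx <- (seq_len(nx) - 0.5) * cs
  gy <- (seq_len(ny) - 0.5) * cs
  cells <- expand.grid(x = gx, y = gy, KEEP.OUT.ATTRS = FALSE)
  lambda <- density_mean(cells$x, cells$y, config)
  pop <- stats::rpois(nrow(cells), lambda)
  keep <- pop > 0
  demand_set(data.frame(id = paste0("d", which(keep)),
                        x = cells$x[keep], y = cells$y[keep],
                        pop = pop[keep]))
}

#' Generate clustered supply sites
#'
#' Each site is placed population-proportionally (at a populated cell
#' centroid, probability = `clustering`) or uniformly over the extent;
#' capacities are uniform integers from `capacity_range`.
#'
#' @param config A [scenario_config()].
#' @param grid The demand set from [make_population_grid()].
#' @return A [supply_set()] with ids `s1, s2, ...`.
#' @export
make_supply_sites <- function(config, grid) {
  stopifnot(inherits(config, "scenario_config"))
  if (nrow(grid) == 0L) stop("empty population grid")
  set.seed(config$seed + 1L)
  n <- config$n_supply
  from_pop <- stats::runif(n) < config$clustering
  x <- y <- numeric(n)
  if (any(from_pop)) {
    idx <- sample.int(nrow(grid), sum(from_pop), replace = TRUE,
                      prob = grid$pop)
    x[from_pop] <- grid$x[idx]
    y[from_pop] <- grid$y[idx]
  }
  if (any(!from_pop)) {
    x[!from_pop] <- stats::runif(sum(!from_pop), 0, config$extent[1])
    y[!from_pop] <- stats::runif(sum(!from_pop), 0, config$extent[2])
  }
  cap_vals <- seq(config$capacity_range[1], config$capacity_range[2])
  caps <- cap_vals[sample.int(length(cap_vals), n, replace = TRUE)]
  supply_set(data.frame(id = paste0("s", seq_len(n)), x = x, y = y,
                        capacity = caps))
}

#' Generate a lattice road network with one-way streets
#'
#' Nodes at lattice points over the extent; each street (undirected
#' neighbour link) gets a speed limit sampled from `speed_classes` and is
#' emitted as two directed edges, except for a seeded fraction made one-way
#' by dropping one direction. One-way injection is repaired so the largest
#' strongly connected component keeps at least 95% of the nodes.
#'
#' @param config A [scenario_config()].
#' @return A [road_network()] with node ids `n1, n2, ...`.
#' @export
make_lattice_network <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed + 2L)
  sp <- config$lattice_spacing
  nx <- floor(config$extent[1] / sp) + 1L
  ny <- floor(config$extent[2] / sp) + 1L
  if (nx < 2L || ny < 2L) stop("degenerate lattice: need at least 2 nodes per axis")
  node_at <- function(ix, iy) (iy - 1L) * nx + ix
  nodes <- data.frame(node_id = paste0("n", seq_len(nx * ny)),
                      x = rep((seq_len(nx) - 1L) * sp, ny),
                      y = rep((seq_len(ny) - 1L) * sp, each = nx))
  # undirected streets between 4-neighbours
  h <- expand.grid(ix = seq_len(nx - 1L), iy = seq_len(ny), KEEP.OUT.ATTRS = FALSE)
  v <- expand.grid(ix = seq_len(nx), iy = seq_len(ny - 1L), KEEP.OUT.ATTRS = FALSE)
  streets <- rbind(
    data.frame(a = node_at(h$ix, h$iy), b = node_at(h$ix + 1L, h$iy)),
    data.frame(a = node_at(v$ix, v$iy), b = node_at(v$ix, v$iy + 1L))
  )
  sc <- config$speed_classes  # guard against scalar sample() semantics
  streets$speed <- sc[sample.int(length(sc), nrow(streets), replace = TRUE)]
  n_oneway <- floor(config$oneway_frac * nrow(streets))
  oneway <- rep(FALSE, nrow(streets))
  oneway[sample.int(nrow(streets), n_oneway)] <- TRUE
  flip <- stats::runif(nrow(streets)) < 0.5  # which direction a one-way keeps
  build_edges <- function(ow) {
    fwd <- data.frame(from = streets$a, to = streets$b, speed = streets$speed)
    rev <- data.frame(from = streets$b, to = streets$a, speed = streets$speed)
    keep_fwd <- !(ow & flip)
    keep_rev <- !(ow & !flip)
    rbind(fwd[keep_fwd, ], rev[keep_rev, ])
  }
  # repair: demote one-way streets outside the giant strong component until
  # it spans >= 95% of nodes
  for (it in 1:20) {
    ed <- build_edges(oneway)
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(ed$from), to = as.character(ed$to)),
      directed = TRUE, vertices = data.frame(name = as.character(seq_len(nx * ny))))
    comp <- igraph::components(g, mode = "strong")
    if (max(comp$csize) >= 0.95 * nx * ny) break
    giant <- which.max(comp$csize)
    outside <- as.integer(names(comp$membership)[comp$membership != giant])
    oneway[oneway & (streets$a %in% outside | streets$b %in% outside)] <- FALSE
  }
  edges <- build_edges(oneway)
  road_network(nodes,
               data.frame(from_node = paste0("n", edges$from),
                          to_node = paste0("n", edges$to),
                          length_m = sp, speed_kmh = edges$speed))
}

#' Generate a complete synthetic scenario
#'
#' Composes the population-grid, supply-site and network generators under
#' one seed and returns them with the configuration attached.
#'
#' @param config A [scenario_config()] (default: monocentric preset).
#' @return A list of class `fca_scenario` with elements `demand`, `supply`,
#'   `network`, `config`.
#' @examples
#' sc <- make_scenario(scenario_config(seed = 7, extent = c(3000, 3000)))
#' sc$demand[1:3, ]
#' @export
make_scenario <- function(config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  demand <- make_population_grid(config)
  supply <- make_supply_sites(config, demand)
  network <- make_lattice_network(config)
  structure(list(demand = demand, supply = supply, network = network,
                 config = config),
            class = "fca_scenario")
}

#' @export
print.fca_scenario <- function(x, ...) {
  cat(sprintf("Synthetic scenario (seed %d): %d populated cells (%d inhabitants), %d supply sites (capacity %d), %d-node network\n",
              x$config$seed, nrow(x$demand), sum(x$demand$pop),
              nrow(x$supply), sum(x$supply$capacity), nrow(x$network$nodes)))
  invisible(x)
}
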