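# Readers and writers for the plain-text interchange formats: CSV point
# layers (id,x,y,value), GeoJSON point layers, CSV node/edge tables and the
# long-format OD travel-time matrix. Numeric columns are written with 17
# significant digits so a read-write round trip is lossless in double
# precision.

fmt_num <- function(x) {
  out <- formatC(x, digits = 17, format = "g")
  gsub(" ", "", out)
}

write_table_lossless <- function(df, path) {
  out <- df
  for (cn in names(out)) if (is.numeric(out[[cn]])) out[[cn]] <- fmt_num(out[[cn]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

#' Read a point layer
#'
#' Accepts CSV with header `id,x,y,value` or a GeoJSON FeatureCollection of
#' Point features carrying a numeric `value` property (and optionally an
#' `id`). `value` is the inhabitant count for demand layers and the capacity
#' for supply layers.
#'
#' @param path File path (`.csv`, `.json` or `.geojson`).
#' @param kind `"demand"` or `"supply"`; controls validation.
#' @param aggregate For supply layers, sum the capacities of sites at
#'   identical coordinates into one site. Default `FALSE`.
#' @return A [demand_set()] or [supply_set()].
#' @export
read_points <- function(path, kind = c("demand", "supply"), aggregate = FALSE) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.(geo)?json$", path, ignore.case = TRUE)) {
    gj <- jsonlite::read_json(path)
    if (is.null(gj$features)) stop("GeoJSON must be a FeatureCollection: ", path)
    rows <- lapply(seq_along(gj$features), function(k) {
      f <- gj$features[[k]]
      if (is.null(f$geometry) || !identical(f$geometry$type, "Point"))
        stop(sprintf("feature %d is not a Point", k))
      val <- f$properties$value
      if (is.null(val) || !is.numeric(val))
        stop(sprintf("feature %d lacks a numeric `value` property", k))
      id <- f$properties$id
      data.frame(id = if (is.null(id)) paste0("p", k) else as.character(id),
                 x = as.numeric(f$geometry$coordinates[[1]]),
                 y = as.numeric(f$geometry$coordinates[[2]]),
                 value = as.numeric(val))
    })
    df <- do.call(rbind, rows)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("id", "x", "y", "value")
    if (!all(need %in% names(df)))
      stop("point CSV must have columns id,x,y,value: ", path)
    for (cn in c("x", "y", "value"))
      if (!is.numeric(df[[cn]])) {
        bad <- which(is.na(suppressWarnings(as.numeric(df[[cn]]))))[1]
        stop(sprintf("non-numeric `%s` at data row %d of %s", cn, bad, path))
      }
  }
  dup <- which(duplicated(df$id))[1]
  if (!is.na(dup)) stop(sprintf("duplicate id %s at data row %d of %s", df$id[dup], dup, path))
  if (kind == "demand") {
    demand_set(data.frame(id = df$id, x = df$x, y = df$y, pop = df$value))
  } else {
    if (aggregate && anyDuplicated(paste(df$x, df$y, sep = "\r"))) {
      key <- paste(df$x, df$y, sep = "\r")
      agg <- rowsum(df$value, group = key, reorder = FALSE)
      first <- !duplicated(key)
      df <- data.frame(id = df$id[first], x = df$x[first], y = df$y[first],
                       value = agg[match(key[first], rownames(agg)), 1L])
    }
    supply_set(data.frame(id = df$id, x = df$x, y = df$y, capacity = df$value))
  }
}

#' Write a point layer as CSV
#'
#' @param points A [demand_set()] or [supply_set()].
#' @param path Output CSV path; columns `id,x,y,value`.
#' @export
write_points <- function(points, path) {
  value <- if (inherits(points, "demand_set")) points$pop else points$capacity
  write_table_lossless(
    data.frame(id = points$id, x = points$x, y = points$y, value = value),
    path)
}

#' Read or write a long-format OD travel-time matrix
#'
#' CSV with header `demand_id,supply_id,minutes`; out-of-catchment pairs
#' have no row.
#'
#' @param path CSV path.
#' @param d_max Catchment threshold the matrix was built with (minutes).
#' @return An [od_matrix()].
#' @export
read_od <- function(path, d_max) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  od_matrix(df, d_max)
}

#' @rdname read_od
#' @param od An [od_matrix()].
#' @export
write_od <- function(od, path) {
  write_table_lossless(as.data.frame(od), path)
}

#' Read a road network from node and edge CSV files
#'
#' Nodes: `node_id,x,y`. Edges: `from_node,to_node,length_m,speed_kmh,oneway`
#' with `oneway` 0 or 1; a 0 emits both directions, a 1 only the stated one.
#'
#' @param nodes_path,edges_path CSV paths.
#' @return A [road_network()].
#' @export
read_network <- function(nodes_path, edges_path) {
  nodes <- utils::read.csv(nodes_path, stringsAsFactors = FALSE)
  edges <- utils::read.csv(edges_path, stringsAsFactors = FALSE)
  need <- c("from_node", "to_node", "length_m", "speed_kmh", "oneway")
  if (!all(need %in% names(edges)))
    stop("edge CSV must have columns from_node,to_node,length_m,speed_kmh,oneway")
  two_way <- edges[edges$oneway == 0, ]
  rev <- data.frame(from_node = two_way$to_node, to_node = two_way$from_node,
                    length_m = two_way$length_m, speed_kmh = two_way$speed_kmh)
  all_edges <- rbind(edges[c("from_node", "to_node", "length_m", "speed_kmh")], rev)
  road_network(nodes, all_edges)
}

#' Write a road network to node and edge CSV files
#'
#' Directed edges whose reverse twin exists with the same length and speed
#' are collapsed to a single `oneway = 0` row.
#'
#' @param network A [road_network()].
#' @param nodes_path,edges_path Output CSV paths.
#' @export
write_network <- function(network, nodes_path, edges_path) {
  write_table_lossless(network$nodes, nodes_path)
  e <- network$edges
  key <- paste(e$from_node, e$to_node, e$length_m, e$speed_kmh, sep = "\r")
  rkey <- paste(e$to_node, e$from_node, e$length_m, e$speed_kmh, sep = "\r")
  has_rev <- rkey %in% key
  first_dir <- !has_rev | as.character(e$from_node) < as.character(e$to_node) |
    (as.character(e$from_node) == as.character(e$to_node))
  keep <- e[first_dir, c("from_node", "to_node", "length_m", "speed_kmh")]
  keep$oneway <- as.integer(!has_rev[first_dir])
  write_table_lossless(keep, edges_path)
}

#' Write a scenario's layers to a directory
#'
#' Emits `demand.csv`, `supply.csv`, `nodes.csv`, `edges.csv` and a
#' `scenario.json` configuration record.
#'
#' @param scenario An `fca_scenario` from [make_scenario()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "fca_scenario"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_points(scenario$demand, file.path(dir, "demand.csv"))
  write_points(scenario$supply, file.path(dir, "supply.csv"))
  write_network(scenario$network, file.path(dir, "nodes.csv"),
                file.path(dir, "edges.csv"))
  cfg <- unclass(scenario$config)
  cfg$centers <- as.data.frame(cfg$centers)
  jsonlite::write_json(cfg, file.path(dir, "scenario.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

#' Quantile classification
#'
#' Assigns each value to one of `k` classes bounded by the empirical
#' quantiles at probabilities `1/k, ..., (k-1)/k` (linear-interpolation
#' quantile definition). A value equal to a boundary goes to the lower
#' class; the minimum is always class 1 and the maximum class `k`. When all
#' values coincide the breaks are degenerate: everything is class 1 and a
#' warning is raised.
#'
#' @param values Numeric vector, length >= `k`.
#' @param k Number of classes, >= 2. Default 5 (quintiles, the usual
#'   choropleth convention: dark blue for low through dark red for high).
#' @return Integer class labels in `1..k`.
#' @export
quantile_classify <- function(values, k = 5) {
  if (!is.numeric(k) || length(k) != 1L || k < 2) stop("`k` must be >= 2")
  if (length(values) < k) stop("need at least `k` values to form `k` classes")
  inner <- stats::quantile(values, probs = seq_len(k - 1) / k, type = 7,
                           names = FALSE)
  if (any(duplicated(inner)) || all(values == values[1]))
    warning("degenerate quantile breaks; classes collapse")
  cls <- findInterval(values, inner, left.open = TRUE) + 1L
  pmin(cls, as.integer(k))
}

# Truncate (toward zero) to eight decimals and format, the map-label
# convention for these small providers-per-person indices.
format_trunc8 <- function(x) {
  sprintf("%.8f", trunc(x * 1e8) / 1e8)
}

#' Write an accessibility result and its metadata sidecar
#'
#' Emits `access.csv` (`id,x,y,population,A,quantile_class`), `ratios.csv`
#' (`supply_id,R`) and `meta.json` (method, parameters, counts) to `dir`.
#' Index values are written at full precision; only printed summaries are
#' truncated to eight decimals.
#'
#' @param result An `fca_result`.
#' @param dir Output directory (created if missing).
#' @param k Quantile classes for the `quantile_class` column. Default 5.
#' @return `dir`, invisibly.
#' @export
write_result <- function(result, dir, k = 5) {
  stopifnot(inherits(result, "fca_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cls <- quantile_classify(result$demand$A, k)
  write_table_lossless(
    data.frame(id = result$demand$id, x = result$demand$x, y = result$demand$y,
               population = result$demand$pop, A = result$demand$A,
               quantile_class = cls),
    file.path(dir, "access.csv"))
  write_table_lossless(result$ratios, file.path(dir, "ratios.csv"))
  jsonlite::write_json(result$meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
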