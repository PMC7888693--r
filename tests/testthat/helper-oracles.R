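# Independent dense reference implementations, written as literal
# triple-loop transcriptions of the method formulas over full matrices.
# They share no code with the package's sparse pipeline and exist to check
# it on small random instances.

# Dense weight matrix: NA entries of tmat are out of catchment -> weight 0.
oracle_weights <- function(tmat, params) {
  w <- matrix(0, nrow(tmat), ncol(tmat))
  for (i in seq_len(nrow(tmat))) for (j in seq_len(ncol(tmat))) {
    if (!is.na(tmat[i, j])) {
      d <- tmat[i, j]
      if (params$mode == "continuous") {
        w[i, j] <- exp(-d^2 / params$beta)
      } else {
        width <- params$d_max / params$n_zones
        z <- min(floor(d / width) + 1, params$n_zones)
        mid <- (z - 0.5) * width
        w[i, j] <- exp(-mid^2 / params$beta)
      }
    }
  }
  w
}

oracle_mh3sfca <- function(tmat, S, D, params) {
  n_i <- nrow(tmat); n_j <- ncol(tmat)
  w <- oracle_weights(tmat, params)
  huff <- matrix(0, n_i, n_j)
  for (i in seq_len(n_i)) {
    denom <- 0
    for (k in seq_len(n_j)) if (!is.na(tmat[i, k])) denom <- denom + S[k] * w[i, k]
    if (denom > 0)
      for (j in seq_len(n_j)) if (!is.na(tmat[i, j]))
        huff[i, j] <- S[j] * w[i, j] / denom
  }
  R <- numeric(n_j)
  for (j in seq_len(n_j)) {
    denom <- 0
    for (i in seq_len(n_i)) if (!is.na(tmat[i, j])) denom <- denom + huff[i, j] * D[i]
    R[j] <- if (denom > 0) S[j] / denom else 0
  }
  A <- numeric(n_i)
  for (i in seq_len(n_i))
    for (j in seq_len(n_j)) if (!is.na(tmat[i, j]))
      A[i] <- A[i] + huff[i, j] * R[j] * w[i, j]
  list(A = A, R = R, huff = huff, w = w)
}

oracle_2sfca <- function(tmat, S, D) {
  n_i <- nrow(tmat); n_j <- ncol(tmat)
  R <- numeric(n_j)
  for (j in seq_len(n_j)) {
    denom <- 0
    for (i in seq_len(n_i)) if (!is.na(tmat[i, j])) denom <- denom + D[i]
    R[j] <- if (denom > 0) S[j] / denom else 0
  }
  A <- numeric(n_i)
  for (i in seq_len(n_i))
    for (j in seq_len(n_j)) if (!is.na(tmat[i, j])) A[i] <- A[i] + R[j]
  list(A = A, R = R)
}

oracle_e2sfca <- function(tmat, S, D, params) {
  w <- oracle_weights(tmat, params)
  n_i <- nrow(tmat); n_j <- ncol(tmat)
  R <- numeric(n_j)
  for (j in seq_len(n_j)) {
    denom <- 0
    for (i in seq_len(n_i)) if (!is.na(tmat[i, j])) denom <- denom + D[i] * w[i, j]
    R[j] <- if (denom > 0) S[j] / denom else 0
  }
  A <- numeric(n_i)
  for (i in seq_len(n_i))
    for (j in seq_len(n_j)) if (!is.na(tmat[i, j])) A[i] <- A[i] + R[j] * w[i, j]
  list(A = A, R = R)
}

oracle_3sfca <- function(tmat, S, D, params) {
  w <- oracle_weights(tmat, params)
  n_i <- nrow(tmat); n_j <- ncol(tmat)
  g <- matrix(0, n_i, n_j)
  for (i in seq_len(n_i)) {
    denom <- 0
    for (k in seq_len(n_j)) if (!is.na(tmat[i, k])) denom <- denom + w[i, k]
    if (denom > 0)
      for (j in seq_len(n_j)) if (!is.na(tmat[i, j])) g[i, j] <- w[i, j] / denom
  }
  R <- numeric(n_j)
  for (j in seq_len(n_j)) {
    denom <- 0
    for (i in seq_len(n_i)) if (!is.na(tmat[i, j]))
      denom <- denom + g[i, j] * D[i] * w[i, j]
    R[j] <- if (denom > 0) S[j] / denom else 0
  }
  A <- numeric(n_i)
  for (i in seq_len(n_i))
    for (j in seq_len(n_j)) if (!is.na(tmat[i, j]))
      A[i] <- A[i] + g[i, j] * R[j] * w[i, j]
  list(A = A, R = R)
}

oracle_m2sfca <- function(tmat, S, D, params) {
  w <- oracle_weights(tmat, params)
  n_i <- nrow(tmat); n_j <- ncol(tmat)
  A <- numeric(n_i)
  R <- numeric(n_j)
  for (j in seq_len(n_j)) {
    denom <- 0
    for (k in seq_len(n_i)) if (!is.na(tmat[k, j])) denom <- denom + D[k] * w[k, j]
    R[j] <- if (denom > 0) S[j] / denom else 0
    if (denom > 0)
      for (i in seq_len(n_i)) if (!is.na(tmat[i, j]))
        A[i] <- A[i] + S[j] * w[i, j]^2 / denom
  }
  list(A = A, R = R)
}

# Brute-force all-pairs shortest paths (Floyd-Warshall) on a directed
# weighted edge list; the independent check for the Dijkstra-based OD matrix.
oracle_shortest_paths <- function(n_nodes, edges) {
  dm <- matrix(Inf, n_nodes, n_nodes)
  diag(dm) <- 0
  for (r in seq_len(nrow(edges))) {
    f <- edges$from[r]; t <- edges$to[r]
    dm[f, t] <- min(dm[f, t], edges$w[r])
  }
  for (k in seq_len(n_nodes))
    for (i in seq_len(n_nodes))
      for (j in seq_len(n_nodes))
        if (dm[i, k] + dm[k, j] < dm[i, j]) dm[i, j] <- dm[i, k] + dm[k, j]
  dm
}

# Random small supply/demand instance with a thresholded travel-time
# structure, in both the sparse (package) and dense (oracle) layouts.
random_instance <- function(seed, d_max = 30, allow_zero_pop = TRUE,
                            force_distance = NULL) {
  set.seed(seed)
  n_i <- sample(2:30, 1)
  n_j <- sample(1:20, 1)
  D <- if (allow_zero_pop) rpois(n_i, 40) else rpois(n_i, 40) + 1L
  S <- sample(1:5, n_j, replace = TRUE)
  tmat <- matrix(NA_real_, n_i, n_j)
  for (i in seq_len(n_i)) for (j in seq_len(n_j)) {
    t_ij <- runif(1, 0, d_max * 1.5)
    if (!is.null(force_distance)) t_ij <- force_distance
    if (t_ij <= d_max) tmat[i, j] <- t_ij
  }
  pairs <- which(!is.na(tmat), arr.ind = TRUE)
  od <- od_matrix(data.frame(demand_id = paste0("i", pairs[, 1]),
                             supply_id = paste0("j", pairs[, 2]),
                             minutes = tmat[pairs]),
                  d_max)
  demand <- demand_set(data.frame(id = paste0("i", seq_len(n_i)),
                                  x = runif(n_i), y = runif(n_i), pop = D))
  supply <- supply_set(data.frame(id = paste0("j", seq_len(n_j)),
                                  x = runif(n_j), y = runif(n_j), capacity = S))
  list(od = od, demand = demand, supply = supply, tmat = tmat, D = D, S = S)
}

# Random connected-ish directed graph for shortest-path checks; a share of
# node pairs gets a forward edge only (one-way streets).
random_digraph <- function(seed, max_nodes = 50) {
  set.seed(seed)
  n <- sample(4:max_nodes, 1)
  m <- sample(n:(3 * n), 1)
  from <- sample.int(n, m, replace = TRUE)
  to <- sample.int(n, m, replace = TRUE)
  keep <- from != to
  from <- from[keep]; to <- to[keep]
  w <- round(runif(length(from), 0.5, 12), 3)
  two_way <- runif(length(from)) < 0.5
  edges <- rbind(data.frame(from = from, to = to, w = w),
                 data.frame(from = to[two_way], to = from[two_way], w = w[two_way]))
  list(n = n, edges = edges)
}

# Align a package result's A vector to i1..in order.
result_A <- function(res) {
  res$demand$A[order(as.integer(sub("^i", "", res$demand$id)))]
}
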