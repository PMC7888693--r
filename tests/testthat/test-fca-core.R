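params30 <- decay_params(30, 0.01)

test_that("Huff probabilities are capacity-weighted shares that sum to one per location", {
  # one demand, one reachable supply: probability 1 regardless of distance
  sup1 <- supply_set(data.frame(id = "j1", x = 0, y = 0, capacity = 3))
  od1 <- od_matrix(data.frame(demand_id = "i1", supply_id = "j1", minutes = 17), 30)
  it1 <- build_interactions(od1, sup1, params30)
  expect_equal(it1$huff, 1)

  # S = (2, 1), W = (0.5, 0.25) -> Huff = (0.8, 0.2)
  b <- 100
  p <- decay_params(d_max = 30, beta = b)
  d1 <- sqrt(b * log(2)); d2 <- sqrt(b * log(4))
  sup <- supply_set(data.frame(id = c("j1", "j2"), x = 0:1, y = 0,
                               capacity = c(2, 1)))
  od <- od_matrix(data.frame(demand_id = "i1", supply_id = c("j1", "j2"),
                             minutes = c(d1, d2)), 30)
  it <- build_interactions(od, sup, p)
  expect_equal(it$weight, c(0.5, 0.25), tolerance = 1e-12)
  expect_equal(it$huff, c(0.8, 0.2), tolerance = 1e-12)

  # identical distances: weights cancel, shares reduce to capacity shares
  sup3 <- supply_set(data.frame(id = paste0("j", 1:3), x = 1:3, y = 0,
                                capacity = c(1, 2, 5)))
  od3 <- od_matrix(data.frame(demand_id = rep(c("i1", "i2"), each = 3),
                              supply_id = rep(paste0("j", 1:3), 2),
                              minutes = 12), 30)
  it3 <- build_interactions(od3, sup3, params30)
  expect_equal(it3$huff, rep(c(1, 2, 5) / 8, 2), tolerance = 1e-12)

  # normalisation holds on random instances
  for (seed in 1:25) {
    inst <- random_instance(seed)
    it <- build_interactions(inst$od, inst$supply, params30)
    sums <- rowsum(it$huff, it$demand_id)
    expect_lt(max(abs(sums - 1)), 1e-12)
  }
})

test_that("supply-demand ratios divide capacity by Huff-allocated demand", {
  sup <- supply_set(data.frame(id = "j1", x = 0, y = 0, capacity = 2))
  dem <- demand_set(data.frame(id = c("i1", "i2"), x = 0:1, y = 0,
                               pop = c(100, 300)))
  inter <- data.frame(demand_id = c("i1", "i2"), supply_id = "j1",
                      minutes = c(1, 2), weight = c(1, 1), huff = c(0.8, 0.5))
  r <- supply_demand_ratio(inter, sup, dem)
  expect_equal(unname(r), 2 / 230, tolerance = 1e-12)  # denominator 80 + 150

  # one covered location with full allocation
  dem2 <- demand_set(data.frame(id = "i1", x = 0, y = 0, pop = 500))
  sup2 <- supply_set(data.frame(id = "j1", x = 0, y = 0, capacity = 1))
  inter2 <- data.frame(demand_id = "i1", supply_id = "j1", minutes = 0,
                       weight = 1, huff = 1)
  expect_equal(unname(supply_demand_ratio(inter2, sup2, dem2)), 0.002)

  # a site with no reachable population is flagged with ratio 0
  sup3 <- supply_set(data.frame(id = c("j1", "j2"), x = 0:1, y = 0,
                                capacity = c(1, 4)))
  expect_warning(r3 <- supply_demand_ratio(inter2, sup3, dem2), "no allocated demand")
  expect_equal(unname(r3["j2"]), 0)
})

test_that("accessibility index sums Huff-, ratio- and distance-weighted shares", {
  dem <- demand_set(data.frame(id = "i1", x = 0, y = 0, pop = 10))
  inter <- data.frame(demand_id = c("i1", "i1"), supply_id = c("j1", "j2"),
                      minutes = c(1, 2), weight = c(0.5, 0.25),
                      huff = c(0.8, 0.2))
  r <- c(j1 = 0.01, j2 = 0.02)
  a <- accessibility_index(inter, r, dem)
  expect_equal(unname(a), 0.8 * 0.01 * 0.5 + 0.2 * 0.02 * 0.25)  # 0.005

  # co-located single pair collapses to the raw supply-demand ratio
  sup <- supply_set(data.frame(id = "j1", x = 0, y = 0, capacity = 3))
  dem2 <- demand_set(data.frame(id = "i1", x = 0, y = 0, pop = 600))
  od <- od_matrix(data.frame(demand_id = "i1", supply_id = "j1", minutes = 0), 30)
  res <- mh3sfca(od, sup, dem2, params30)
  expect_equal(res$demand$A, 3 / 600, tolerance = 1e-15)

  # a location with no in-catchment supply gets index zero
  dem3 <- demand_set(data.frame(id = c("i1", "i2"), x = 0:1, y = 0,
                                pop = c(600, 50)))
  res3 <- mh3sfca(od, sup, dem3, params30)
  expect_equal(res3$demand$A[res3$demand$id == "i2"], 0)
  expect_equal(res3$meta$n_uncovered_demand, 1L)
})

test_that("uniform-distance system has the closed-form index exp(-d^2/beta) * sum(S)/sum(D)", {
  set.seed(3)
  n_i <- 6; n_j <- 4
  dem <- demand_set(data.frame(id = paste0("i", 1:n_i), x = runif(n_i),
                               y = runif(n_i), pop = rpois(n_i, 50) + 1))
  sup <- supply_set(data.frame(id = paste0("j", 1:n_j), x = runif(n_j),
                               y = runif(n_j), capacity = sample(1:4, n_j, TRUE)))
  for (d in c(0, 5, 15, 30)) {
    od <- od_matrix(expand.grid(demand_id = dem$id, supply_id = sup$id,
                                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE) |>
                      transform(minutes = d), 30)
    res <- mh3sfca(od, sup, dem, params30)
    want <- exp(-d^2 / params30$beta) * sum(sup$capacity) / sum(dem$pop)
    expect_equal(res$demand$A, rep(want, n_i), tolerance = 1e-12)
  }
})

test_that("sparse pipeline equals the dense triple-loop reference on random instances", {
  for (seed in 1:30) {
    inst <- random_instance(seed)
    mode_p <- if (seed %% 2) params30 else decay_params(30, 0.01, "subzones", 4)
    res <- suppressWarnings(mh3sfca(inst$od, inst$supply, inst$demand, mode_p))
    orc <- oracle_mh3sfca(inst$tmat, inst$S, inst$D, mode_p)
    expect_lt(max(abs(result_A(res) - orc$A)), 1e-10)
    expect_lt(max(abs(res$ratios$R[order(as.integer(sub("j", "", res$ratios$supply_id)))] -
                        orc$R)), 1e-10)
  }
})

test_that("indices scale linearly with capacity and inversely with population", {
  inst <- random_instance(11, allow_zero_pop = FALSE)
  base <- suppressWarnings(mh3sfca(inst$od, inst$supply, inst$demand, params30))
  sup_c <- inst$supply; sup_c$capacity <- sup_c$capacity * 3
  res_c <- suppressWarnings(mh3sfca(inst$od, supply_set(sup_c), inst$demand, params30))
  expect_equal(res_c$demand$A, base$demand$A * 3, tolerance = 1e-12)
  dem_c <- inst$demand; dem_c$pop <- dem_c$pop * 5
  res_d <- suppressWarnings(mh3sfca(inst$od, inst$supply, demand_set(dem_c), params30))
  expect_equal(res_d$demand$A, base$demand$A / 5, tolerance = 1e-12)
  # Huff shares are invariant under demand scaling
  it1 <- build_interactions(inst$od, inst$supply, params30)
  it2 <- build_interactions(inst$od, supply_set(sup_c), params30)
  expect_equal(it1$huff, it2$huff, tolerance = 1e-14)
})

test_that("empty demand cells receive an index but add nothing to any denominator", {
  sup <- supply_set(data.frame(id = "j1", x = 0, y = 0, capacity = 2))
  dem <- demand_set(data.frame(id = c("i1", "i2"), x = 0:1, y = 0,
                               pop = c(100, 0)))
  od <- od_matrix(data.frame(demand_id = c("i1", "i2"), supply_id = "j1",
                             minutes = c(0, 0)), 30)
  res <- mh3sfca(od, sup, dem, params30)
  expect_equal(res$ratios$R, 2 / 100)          # only i1 contributes demand
  expect_equal(res$demand$A, rep(2 / 100, 2))  # but both have access
})

test_that("inconsistent ids between OD matrix and point sets raise a naming error", {
  sup <- supply_set(data.frame(id = "j1", x = 0, y = 0, capacity = 1))
  dem <- demand_set(data.frame(id = "i1", x = 0, y = 0, pop = 1))
  od_bad_s <- od_matrix(data.frame(demand_id = "i1", supply_id = "jX",
                                   minutes = 1), 30)
  expect_error(mh3sfca(od_bad_s, sup, dem, params30), "jX")
  od_bad_d <- od_matrix(data.frame(demand_id = "iX", supply_id = "j1",
                                   minutes = 1), 30)
  expect_error(mh3sfca(od_bad_d, sup, dem, params30), "iX")
})

test_that("supply sets reject non-positive capacities and duplicate ids", {
  expect_error(supply_set(data.frame(id = "j", x = 0, y = 0, capacity = 0)),
               "positive")
  expect_error(supply_set(data.frame(id = c("j", "j"), x = 0, y = 0,
                                     capacity = 1)), "duplicate")
  expect_error(demand_set(data.frame(id = "i", x = 0, y = 0, pop = -1)),
               "non-negative")
})
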