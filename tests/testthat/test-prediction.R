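chain_system <- function() {
  # one origin, one destination, a single route through station k
  edges <- data.frame(from = c("o", "k"), to = c("k", "d"),
                      travel_time = c(2000, 2000))
  net <- road_network(edges, data.frame(id = c("o", "d", "k"),
                                        role = c("origin", "destination",
                                                 "station")))
  org <- data.frame(id = "o", pop = 5, CA = 1)
  dst <- data.frame(id = "d", A = 500, camp = 1, fac = 0, mar = 0, lpop = 0)
  list(net = net, org = org, dst = dst,
       dmat = shortest_distance(net, "o", "d"),
       ps = admissible_path_sets(net, "o", "d"))
}

test_that("a single admissible route carries the whole admissible flow", {
  sys <- chain_system()
  g <- bc_boater_params()$gravity
  r <- route_choice_params(7.4, eta_c = 0.049, eta_o = 0.062)
  flows <- predict_flows(g, r, sys$org, sys$dst, sys$dmat, sys$ps)
  mu <- mean_flow(g, sys$org, sys$dst, 4000)
  expect_equal(flows$dest_inflow$mean, mu)
  expect_equal(flows$origin_outflow$outflow, mu)
  expect_equal(sort(flows$edge_flows$flow), rep(mu * (1 - 0.049), 2))
  expect_equal(flows$unallocated, 0.049 * mu)
  expect_equal(flows$dest_inflow$q95, qnbmv(0.95, mu, g$p))
})

test_that("equal-length alternatives split the flow evenly", {
  edges <- data.frame(from = c("o", "o", "a", "b"),
                      to = c("a", "b", "d", "d"),
                      travel_time = c(1500, 1500, 1500, 1500))
  net <- road_network(edges)
  ps <- admissible_path_sets(net, "o", "d", gamma = 1.4, delta = 0)
  g <- bc_boater_params()$gravity
  r <- route_choice_params(7.4, 0, 0)
  org <- data.frame(id = "o", pop = 5, CA = 1)
  dst <- data.frame(id = "d", A = 500, camp = 1, fac = 0, mar = 0, lpop = 0)
  flows <- predict_flows(g, r, org, dst,
                         shortest_distance(net, "o", "d"), ps)
  mu <- flows$total
  up <- flows$edge_flows[flows$edge_flows$from == "o", ]
  expect_equal(sort(up$to), c("a", "b"))
  expect_equal(up$flow, rep(mu / 2, 2))
})

test_that("flow across any origin-separating cut equals the admissible flow", {
  net <- road_network(fig_topology())
  ps <- admissible_path_sets(net, "s", "t", gamma = 1.6, delta = 0)
  g <- bc_boater_params()$gravity
  r <- route_choice_params(2, eta_c = 0.04, eta_o = 0.1)
  org <- data.frame(id = "s", pop = 3, CA = 1)
  dst <- data.frame(id = "t", A = 800, camp = 1, fac = 1, mar = 1, lpop = 10)
  flows <- predict_flows(g, r, org, dst,
                         shortest_distance(net, "s", "t"), ps)
  mu <- flows$total
  # cut {s}: edges s->t and s->u
  cut1 <- sum(flows$edge_flows$flow[flows$edge_flows$from == "s"])
  expect_equal(cut1, mu * (1 - 0.04), tolerance = 1e-12)
  # cut {s,u,w}: edges s->t, u->v, w->v
  ef <- flows$edge_flows
  cut2 <- sum(ef$flow[paste(ef$from, ef$to) %in% c("s t", "u v", "w v")])
  expect_equal(cut2, mu * (1 - 0.04), tolerance = 1e-12)
})

test_that("share tables rank and accumulate flows", {
  mk <- function(means) structure(
    list(dest_inflow = data.frame(destination = paste0("d", seq_along(means)),
                                  mean = means),
         origin_outflow = data.frame(origin = "o", outflow = sum(means))),
    class = "flow_summary")
  one <- share_table(mk(c(0, 5, 0)))
  expect_equal(one$cum_share[1], 1)
  expect_equal(one$id[1], "d2")
  unif <- share_table(mk(rep(2, 8)))
  expect_equal(unif$cum_share, (1:8) / 8)
  # invariance under relabelling
  perm <- share_table(mk(c(4, 1, 3)))
  expect_equal(perm$flow, c(4, 3, 1))
})

test_that("variance-corrected R2 hits its anchor values", {
  org <- "a"; dst <- "x"
  mu <- matrix(12, 1, 1, dimnames = list(org, dst))
  rho <- matrix(c(1, 0.5), 1, 2, dimnames = list("a|x", c("k1", "k2")))
  tp <- temporal_params(12, 0)   # tau = 4/24 = 1/6 for an 11-15 window
  shifts <- data.frame(shift = paste0("s", 1:4),
                       station = c("k1", "k1", "k2", "k2"),
                       start = 11, end = 15)
  # predicted means: 12 * 1/6 = 2 at k1, 1 at k2; observed equal: R2 = 1
  perfect <- count_data(shifts,
                        data.frame(shift = shifts$shift,
                                   origin = "a", destination = "x",
                                   count = c(2L, 2L, 1L, 1L)),
                        org, dst)
  expect_equal(as.numeric(variance_corrected_r2(perfect, mu, 0.23, rho,
                                                tp, 1)), 1)
  # observations symmetric around a common prediction: R2 = 0
  rho0 <- matrix(c(1, 1), 1, 2, dimnames = list("a|x", c("k1", "k2")))
  sym <- count_data(shifts,
                    data.frame(shift = shifts$shift, origin = "a",
                               destination = "x",
                               count = c(3L, 3L, 1L, 1L)),
                    org, dst)
  expect_equal(as.numeric(variance_corrected_r2(sym, mu, 0.23, rho0,
                                                tp, 1)), 0, tolerance = 1e-12)
  # a single station is undefined
  one <- count_data(shifts[1:2, ],
                    data.frame(shift = "s1", origin = "a",
                               destination = "x", count = 2L), org, dst)
  expect_error(variance_corrected_r2(one, mu, 0.23, rho, tp, 1), "2 stations")
})

test_that("Nagelkerke pseudo R2 follows its closed form", {
  # hand-checked small case
  l0 <- -10; l1 <- -5; n <- 10
  want <- (1 - (exp(l0) / exp(l1))^(2 / n)) / (1 - exp(l0)^(2 / n))
  expect_equal(nagelkerke_pseudo_r2(l1, l0, n), want, tolerance = 1e-12)
  # model equal to the null explains nothing
  expect_equal(nagelkerke_pseudo_r2(l0, l0, n), 0)
  # a model worse than the null warns
  expect_warning(r <- nagelkerke_pseudo_r2(-11, -10, 10), "lower")
  expect_lt(r, 0)
})
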