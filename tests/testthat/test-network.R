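test_that("shortest distances handle identity, single edges and symmetry", {
  net <- road_network(data.frame(from = "s", to = "t", travel_time = 7))
  expect_equal(as.numeric(shortest_distance(net, "s", "s")), 0)
  expect_equal(as.numeric(shortest_distance(net, "s", "t")), 7)
  expect_equal(as.numeric(shortest_distance(net, "t", "s")), 7)
})

test_that("invalid networks are rejected", {
  expect_error(road_network(data.frame(from = "a", to = "b",
                                       travel_time = -1)), "positive")
  expect_error(road_network(data.frame(from = "a", to = "b",
                                       travel_time = Inf)), "positive")
  expect_error(road_network(data.frame(from = "a", to = "b",
                                       travel_time = 1),
                            data.frame(id = "zz", role = "station")),
               "not present")
})

test_that("shortest distances equal exhaustive path enumeration", {
  set.seed(101)
  for (rep in 1:10) {
    n <- sample(5:10, 1)
    edges <- rand_graph(n)
    net <- road_network(edges)
    verts <- sample(unique(c(edges$from, edges$to)), 3)
    for (a in verts) for (b in verts)
      expect_equal(as.numeric(shortest_distance(net, a, b)),
                   shortest_bf(edges, a, b), tolerance = 1e-10)
  }
})

test_that("unreachable pairs are flagged with infinite distance", {
  edges <- data.frame(from = c("a", "c"), to = c("b", "d"),
                      travel_time = c(1, 1))
  net <- road_network(edges)
  expect_equal(as.numeric(shortest_distance(net, "a", "d")), Inf)
  ap <- enumerate_admissible_paths(net, "a", "d")
  expect_true(ap$unreachable)
  expect_length(ap$paths, 0)
})

test_that("the illustration topology admits the right paths", {
  net <- road_network(fig_topology())
  # moderate delta: direct road and the u-v alternative are admissible,
  # the local detour via w is excluded even though it meets the stretch
  ap <- enumerate_admissible_paths(net, "s", "t", gamma = 1.6, delta = 0.6)
  expect_setequal(path_key_set(ap$paths), c("s>t", "s>u>v>t"))
  # delta = 1: every subpath must be shortest, only the direct road remains
  ap1 <- enumerate_admissible_paths(net, "s", "t", gamma = 1.6, delta = 1)
  expect_equal(path_key_set(ap1$paths), "s>t")
  # delta = 0: no local-optimality constraint, the detour via w comes back
  ap0 <- enumerate_admissible_paths(net, "s", "t", gamma = 1.6, delta = 0)
  expect_setequal(path_key_set(ap0$paths), c("s>t", "s>u>v>t", "s>u>w>v>t"))
  expect_equal(ap0$lengths, c(3.5, 4, 5))
})

test_that("admissible enumeration equals the brute-force filter", {
  set.seed(202)
  for (rep in 1:30) {
    n <- sample(5:12, 1)
    edges <- rand_graph(n, extra_edges = n + 3)
    net <- road_network(edges)
    verts <- unique(c(edges$from, edges$to))
    st <- sample(verts, 2)
    gamma <- stats::runif(1, 1, 2)
    delta <- stats::runif(1)
    got <- enumerate_admissible_paths(net, st[1], st[2], gamma, delta)
    want <- admissible_bf(edges, st[1], st[2], gamma, delta)
    expect_equal(path_key_set(got$paths), path_key_set(want))
  }
})

test_that("the shortest path survives every admissibility filter", {
  set.seed(303)
  for (rep in 1:10) {
    edges <- rand_graph(8)
    net <- road_network(edges)
    verts <- unique(c(edges$from, edges$to))
    st <- sample(verts, 2)
    ap <- enumerate_admissible_paths(net, st[1], st[2],
                                     gamma = 1, delta = 1)
    expect_length(ap$paths, 1)
    expect_equal(ap$lengths[1],
                 as.numeric(shortest_distance(net, st[1], st[2])),
                 tolerance = 1e-10)
  }
})

test_that("admissible sets are monotone in gamma and delta", {
  set.seed(404)
  for (rep in 1:10) {
    edges <- rand_graph(10, extra_edges = 12)
    net <- road_network(edges)
    verts <- unique(c(edges$from, edges$to))
    st <- sample(verts, 2)
    loose <- enumerate_admissible_paths(net, st[1], st[2], 1.8, 0.1)
    tight <- enumerate_admissible_paths(net, st[1], st[2], 1.3, 0.5)
    expect_true(all(path_key_set(tight$paths) %in% path_key_set(loose$paths)))
  }
})

test_that("station incidence excludes pair endpoints", {
  net <- road_network(fig_topology())
  ps <- admissible_path_sets(net, "s", "t", gamma = 1.6, delta = 0)
  inc <- station_incidence(ps, c("u", "s", "t"))
  m <- inc[["s|t"]]
  # u lies on the two indirect paths only; endpoint stations never count
  lens <- ps[["s|t"]]$lengths
  expect_equal(m[, "u"], lens > 3.5)
  expect_false(any(m[, "s"]))
  expect_false(any(m[, "t"]))
})
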