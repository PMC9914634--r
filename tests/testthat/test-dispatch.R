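test_that("locate snaps the demand and returns its home catchment", {
  fix <- make_fixture(fixture_spec(kind = "grid", rows = 4, cols = 4,
                                   facility_count = 3, seed = 8))
  net <- fix$network
  fs <- fix$facilities
  w <- time_weights(net)
  ca <- build_nvd(net, fs, w)
  # demand exactly at a facility anchor -> that facility is home
  a1 <- fs$anchor_node[1]
  i <- match(a1, net$nodes$node_id)
  loc <- locate(ca, dispatch_request(net$nodes$lon[i], net$nodes$lat[i]), net)
  expect_identical(loc$demand_node, a1)
  expect_identical(loc$home_facility, fs$facility_id[1])
  # any labeled node: home equals the oracle argmin facility
  orc <- nvd_oracle(net, fs, w)
  for (node in sample(names(ca$label), 5)) {
    loc <- locate(ca, dispatch_request(node_id = node), net)
    expect_identical(loc$home_facility, unname(orc$label[node]))
  }
})

test_that("demand in a facility-free component raises a no-coverage error", {
  edges <- data.frame(u = c("a", "x"), v = c("b", "y"), length_m = 50)
  net <- abstract_net(edges)
  fs <- anchored_facilities(c(p1 = "a"))
  ca <- build_nvd(net, fs, distance_weights(net), "distance_m")
  expect_error(locate(ca, dispatch_request(node_id = "x"), net),
               "\\[locate\\].*no facility coverage")
})

test_that("candidate set follows home availability and adjacency", {
  adj <- manual_adjacency(list(
    p2 = "p5", p3 = "p5", p4 = "p5", p5 = c("p2", "p3", "p4", "p6", "p7"),
    p6 = "p5", p7 = "p5"))
  all_on <- setNames(rep(1, 6), paste0("p", 2:7))
  # home available: home plus its adjacent facilities
  expect_setequal(candidate_set("p5", adj, all_on),
                  c("p5", "p2", "p3", "p4", "p6", "p7"))
  # home down: exactly the adjacent set {p3, p6, p7, p4, p2}
  off5 <- all_on; off5["p5"] <- 0
  expect_setequal(candidate_set("p5", adj, off5),
                  c("p3", "p6", "p7", "p4", "p2"))
  # home available with 2 neighbors -> 3 candidates
  adj2 <- manual_adjacency(list(pa = c("pb", "pc"), pb = "pa", pc = "pa"))
  expect_length(candidate_set("pa", adj2, c(pa = 1, pb = 1, pc = 1)), 3L)
  # unavailable facilities are never candidates
  some <- all_on; some[c("p5", "p3", "p6")] <- 0
  expect_setequal(candidate_set("p5", adj, some), c("p2", "p4", "p7"))
})

test_that("ring expansion walks the adjacency graph breadth-first", {
  # chain of catchments pA - pB - pC - pD - pE
  chain <- manual_adjacency(list(pA = "pB", pB = c("pA", "pC"),
                                 pC = c("pB", "pD"), pD = c("pC", "pE"),
                                 pE = "pD"))
  avail <- c(pA = 0, pB = 0, pC = 0, pD = 1, pE = 1)
  # home pB: ring 1 {pA, pC} all down; ring 2 {pD} has the unit
  expect_identical(candidate_set("pB", chain, avail), "pD")
  # pE is only reached when pD is down too
  avail["pD"] <- 0
  expect_identical(candidate_set("pB", chain, avail), "pE")
  avail["pE"] <- 0
  expect_error(candidate_set("pB", chain, avail),
               "\\[candidates\\].*no available facility")
})

test_that("ranking matches exhaustive path enumeration on a small fixture", {
  withr::local_seed(31)
  # 3x4 grid, randomized congestion, 5 candidate facilities
  fix <- make_fixture(fixture_spec(kind = "grid", rows = 3, cols = 4,
                                   facility_count = 5,
                                   congestion = c(0, 0.8), seed = 31))
  net <- fix$network
  fs <- fix$facilities
  w <- time_weights(net)
  demand <- "n006"
  ranked <- rank_candidates(net, w, fs$facility_id, demand, fs)
  for (i in seq_len(nrow(ranked))) {
    anchor <- fs$anchor_node[match(ranked$facility_id[i], fs$facility_id)]
    expect_equal(ranked$travel_time_s[i],
                 brute_force_cost(net, w, anchor, demand),
                 tolerance = 1e-9)
    # path starts at the facility anchor and ends at the demand node
    p <- ranked$path[[i]]
    expect_identical(p[1], anchor)
    expect_identical(p[length(p)], demand)
    # path-cost consistency: reported time equals the sum of edge weights
    if (length(p) > 1) {
      cost <- 0
      e <- net$edges
      for (k in seq_len(length(p) - 1)) {
        hit <- which((e$u == p[k] & e$v == p[k + 1]) |
                       (e$v == p[k] & e$u == p[k + 1]))
        cost <- cost + min(w[e$edge_id[hit]])
      }
      expect_equal(ranked$travel_time_s[i], cost, tolerance = 1e-9)
    }
  }
  expect_true(all(diff(ranked$travel_time_s) >= 0))
  # single candidate: plain Dijkstra cost
  one <- rank_candidates(net, w, fs$facility_id[1], demand, fs)
  expect_equal(nrow(one), 1L)
  g <- as_igraph(net, w)
  expect_equal(one$travel_time_s,
               igraph::distances(g, v = fs$anchor_node[1], to = demand,
                                 weights = igraph::E(g)$weight)[1, 1])
})

test_that("with all units available the home facility is dispatched", {
  for (seed in c(2, 9)) {
    fix <- make_fixture(fixture_spec(kind = "random_planar", node_count = 70,
                                     facility_count = 5,
                                     congestion = c(0, 0.8), seed = seed))
    net <- fix$network
    fs <- fix$facilities
    w <- time_weights(net)
    ca <- build_nvd(net, fs, w)
    adj <- adjacency(net, ca)
    g <- as_igraph(net, w)
    for (node in sample(names(ca$label), 15)) {
      res <- dispatch(net, fs, ca, adj, w, dispatch_request(node_id = node),
                      graph = g)
      expect_identical(res$selected$facility_id, unname(ca$label[node]))
      expect_identical(res$selected$source,
                       if (res$selected$facility_id == res$home_facility)
                         "home_catchment" else "adjacent_catchment")
    }
  }
})

test_that("home unavailable falls back to the best adjacent unit", {
  fix <- make_fixture(fixture_spec(kind = "random_planar", node_count = 80,
                                   facility_count = 6,
                                   congestion = c(0, 0.6), seed = 17))
  net <- fix$network
  fs <- fix$facilities
  w <- time_weights(net)
  ca <- build_nvd(net, fs, w)
  adj <- adjacency(net, ca)
  node <- names(ca$label)[10]
  home <- unname(ca$label[node])
  req <- dispatch_request(node_id = node,
                          availability_override = setNames(0, home))
  res <- dispatch(net, fs, ca, adj, w, req)
  expect_true(res$selected$facility_id %in% adj$neighbors[[home]])
  expect_identical(res$selected$source, "adjacent_catchment")
  # exact time-argmin over the constructed candidate set
  avail <- setNames(rep(1, nrow(fs)), fs$facility_id)
  avail[home] <- 0
  cand <- candidate_set(home, adj, avail)
  orc <- argmin_candidate(net, w, cand, node, fs)
  expect_identical(res$selected$facility_id, orc$facility_id)
  expect_equal(res$selected$travel_time_s, orc$travel_time_s,
               tolerance = 1e-12)
  # phase log names all four phases in order
  expect_identical(vapply(res$phase_log, `[[`, character(1), "phase"),
                   c("locate", "candidates", "rank", "select"))
})

test_that("dispatch is deterministic for a fixed fixture", {
  fix <- make_fixture(fixture_spec(kind = "random_planar", node_count = 60,
                                   facility_count = 4,
                                   congestion = c(0, 0.7), seed = 23))
  w <- time_weights(fix$network)
  ca <- build_nvd(fix$network, fix$facilities, w)
  adj <- adjacency(fix$network, ca)
  req <- dispatch_request(lon = fix$demands$lon[1], lat = fix$demands$lat[1])
  r1 <- dispatch(fix$network, fix$facilities, ca, adj, w, req)
  r2 <- dispatch(fix$network, fix$facilities, ca, adj, w, req)
  expect_identical(r1, r2)
})

test_that("route costs sum lengths and times along the path", {
  # two-segment route, 400 m + 600 m at 36 km/h, free flow
  net <- abstract_net(data.frame(u = c("a", "b"), v = c("b", "c"),
                                 length_m = c(400, 600)), speed = 36)
  rc <- route_costs(net, c("a", "b", "c"))
  expect_equal(rc$distance_m, 1000)
  expect_equal(rc$time_s_division, 100)
  expect_equal(rc$time_s_printed, 100)
  expect_equal(rc$time_s_free, 100)
  # same path at uniform saturation 0.70: division time grows, length fixed
  rc70 <- route_costs(net, c("a", "b", "c"), saturation_override = 0.70)
  expect_equal(rc70$distance_m, 1000)
  expect_equal(rc70$time_s_division, 100 / 0.3, tolerance = 1e-9)
  expect_equal(rc70$time_s_printed, 100 * 0.3, tolerance = 1e-9)
  # degenerate and invalid paths
  expect_equal(route_costs(net, "a")$distance_m, 0)
  expect_equal(route_costs(net, character(0))$time_s_division, 0)
  expect_error(route_costs(net, c("a", "c")), "not joined")
})
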