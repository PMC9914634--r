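test_that("edge CSV parsing counts records and applies the default speed", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("edge_id,u,v,length_m,speed_kmh,vehicle_count,k_max",
               "e1,a,b,500,50,,",
               "e2,b,c,800,,,"), f)
  net <- read_network(f, "edge_csv")
  expect_equal(nrow(net$edges), 2L)
  expect_equal(nrow(net$nodes), 3L)
  expect_equal(net$edges$speed_limit_kmh[net$edges$edge_id == "e2"], 40)
  expect_equal(net$edges$speed_source, c("given", "default"))
  # edges with an explicit speed are never altered by the default
  expect_equal(net$edges$speed_limit_kmh[net$edges$edge_id == "e1"], 50)
  # missing optional attributes fall back to free flow / configured k_max
  expect_equal(net$edges$vehicle_count, c(0, 0))
  expect_equal(net$edges$k_max, c(100, 100))
})

test_that("validation rejects malformed networks naming the record", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("edge_id,u,v,length_m", "e1,a,b,0"), f)
  expect_error(read_network(f, "edge_csv"), "e1.*length_m")
  nodes <- data.frame(node_id = c("a", "b"), lon = 0, lat = 0)
  expect_error(
    road_network(nodes, data.frame(edge_id = "e1", u = "a", v = "a",
                                   length_m = 10)),
    "self-loop")
  expect_error(
    road_network(nodes, data.frame(edge_id = "e1", u = "a", v = "z",
                                   length_m = 10)),
    "endpoint")
  expect_error(
    road_network(data.frame(node_id = "a", lon = 200, lat = 0),
                 data.frame(edge_id = character(0), u = character(0),
                            v = character(0), length_m = numeric(0))),
    "WGS84")
})

test_that("network round-trips through both file dialects", {
  fix <- make_fixture(fixture_spec(kind = "random_planar", node_count = 40,
                                   missing_speed_frac = 0.25,
                                   congestion = c(0.1, 0.8), seed = 11))
  net <- fix$network
  csv <- withr::local_tempfile(fileext = ".csv")
  nds <- withr::local_tempfile(fileext = ".csv")
  write_network(net, csv, "edge_csv", nodes_path = nds)
  back <- read_network(csv, "edge_csv", nodes_path = nds)
  expect_identical(back$edges$edge_id, net$edges$edge_id)
  expect_identical(back$edges$u, net$edges$u)
  expect_identical(back$edges$v, net$edges$v)
  expect_equal(back$edges$length_m, net$edges$length_m)
  expect_equal(back$edges$speed_limit_kmh, net$edges$speed_limit_kmh)
  expect_identical(back$edges$speed_source, net$edges$speed_source)
  expect_equal(back$nodes[order(back$nodes$node_id), ]$lon,
               net$nodes[order(net$nodes$node_id), ]$lon)

  gj <- withr::local_tempfile(fileext = ".geojson")
  write_network(net, gj, "geojson_lines")
  back2 <- read_network(gj, "geojson_lines")
  expect_equal(nrow(back2$edges), nrow(net$edges))
  expect_equal(sort(back2$edges$length_m), sort(net$edges$length_m),
               tolerance = 1e-6)
  expect_equal(sum(back2$edges$speed_source == "default"),
               sum(net$edges$speed_source == "default"))
})

test_that("geojson reader deduplicates endpoints and computes lengths", {
  f <- withr::local_tempfile(fileext = ".geojson")
  gj <- list(type = "FeatureCollection", features = list(
    list(type = "Feature", properties = list(speed_kmh = 50),
         geometry = list(type = "LineString",
                         coordinates = list(c(0, 0), c(0.01, 0)))),
    list(type = "Feature", properties = list(),
         geometry = list(type = "LineString",
                         coordinates = list(c(0.01, 0), c(0.01, 0.01))))
  ))
  jsonlite::write_json(gj, f, auto_unbox = TRUE, digits = NA)
  net <- read_network(f, "geojson_lines")
  expect_equal(nrow(net$nodes), 3L)  # shared endpoint merged
  # length from geometry: ~0.01 degrees of longitude at the equator
  expect_equal(net$edges$length_m[1], 1113.2, tolerance = 0.01)
  expect_equal(net$edges$speed_source, c("given", "default"))
})

test_that("snapping returns the nearest node with lexicographic tie-break", {
  nodes <- data.frame(node_id = c("b", "a"), lon = c(0.01, -0.01), lat = 0)
  net <- road_network(nodes, data.frame(edge_id = "e1", u = "a", v = "b",
                                        length_m = 2000))
  expect_identical(snap_point(net, 0.01, 0), "b")   # exact hit
  expect_identical(snap_point(net, 0, 0), "a")      # equidistant -> lex min
})

test_that("snapping the grid centroid matches an exhaustive distance scan", {
  fix <- make_fixture(fixture_spec(kind = "grid", rows = 3, cols = 3,
                                   seed = 3))
  net <- fix$network
  qlon <- mean(net$nodes$lon)
  qlat <- mean(net$nodes$lat)
  d <- geosphere::distHaversine(c(qlon, qlat),
                                cbind(net$nodes$lon, net$nodes$lat))
  oracle <- sort(net$nodes$node_id[d == min(d)], method = "radix")[1]
  got <- snap_point(net, qlon, qlat)
  expect_identical(got, oracle)
  expect_identical(got, "n005")  # center of the 3x3 grid
})

test_that("snap agrees with the exhaustive scan on random networks", {
  for (seed in 1:5) {
    fix <- make_fixture(fixture_spec(kind = "random_planar", node_count = 60,
                                     demand_count = 8, seed = seed))
    net <- fix$network
    for (i in seq_len(nrow(fix$demands))) {
      d <- geosphere::distHaversine(
        c(fix$demands$lon[i], fix$demands$lat[i]),
        cbind(net$nodes$lon, net$nodes$lat))
      oracle <- sort(net$nodes$node_id[d == min(d)], method = "radix")[1]
      expect_identical(snap_point(net, fix$demands$lon[i],
                                  fix$demands$lat[i]), oracle)
    }
  }
})

test_that("facility snapping anchors every facility and flags shared anchors", {
  fix <- make_fixture(fixture_spec(kind = "random_planar", node_count = 80,
                                   facility_count = 12, seed = 5))
  fs <- fix$facilities
  expect_equal(nrow(fs), 12L)
  expect_false(anyNA(fs$anchor_node))
  expect_true(all(fs$anchor_node %in% fix$network$nodes$node_id))
  # two facilities at the same coordinates share an anchor, with a warning
  dup <- facility_set(data.frame(
    facility_id = c("pA", "pB"),
    lon = fix$network$nodes$lon[1], lat = fix$network$nodes$lat[1],
    available = 1L))
  expect_warning(snapped <- snap_facilities(fix$network, dup),
                 "share anchor")
  expect_identical(snapped$anchor_node[1], snapped$anchor_node[2])
})

test_that("connected components partition the node set", {
  fix <- make_fixture(fixture_spec(kind = "grid", rows = 4, cols = 4,
                                   seed = 1))
  expect_length(connected_components(fix$network), 1L)

  # two disjoint triangles plus an isolated node
  nodes <- data.frame(node_id = c("a", "b", "c", "x", "y", "z", "solo"),
                      lon = NA_real_, lat = NA_real_)
  edges <- data.frame(edge_id = paste0("e", 1:6),
                      u = c("a", "b", "c", "x", "y", "z"),
                      v = c("b", "c", "a", "y", "z", "x"),
                      length_m = 100)
  net <- road_network(nodes, edges)
  comps <- connected_components(net)
  expect_length(comps, 3L)
  sizes <- sort(vapply(comps, length, integer(1)))
  expect_equal(sizes, c(1L, 3L, 3L))
  expect_true(list("solo") %in% comps)
  expect_setequal(unlist(comps), nodes$node_id)
})
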