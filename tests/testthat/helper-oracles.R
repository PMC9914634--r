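# Independent oracles and tiny hand-built graphs used across the suite.
# The oracles deliberately take different routes than the implementation:
# catchment labels come from per-facility single-source Dijkstra (igraph)
# instead of the package's one multi-source sweep, and candidate ranking is
# checked by exhaustive simple-path enumeration.

# Per-facility argmin oracle for the network Voronoi diagram: run one
# single-source Dijkstra per facility anchor, take the cheapest facility per
# node, break exact cost ties by lexicographically smallest facility_id.
nvd_oracle <- function(net, fs, weights) {
  g <- as_igraph(net, weights)
  fac <- sort(fs$facility_id, method = "radix")
  anchors <- fs$anchor_node[match(fac, fs$facility_id)]
  D <- igraph::distances(g, v = unique(anchors),
                         weights = igraph::E(g)$weight,
                         algorithm = "dijkstra")
  D <- D[match(anchors, unique(anchors)), , drop = FALSE]  # row per facility
  nodes <- colnames(D)
  label <- character(0)
  dist <- numeric(0)
  unreachable <- character(0)
  for (j in seq_along(nodes)) {
    d <- D[, j]
    if (!any(is.finite(d))) {
      unreachable <- c(unreachable, nodes[j])
      next
    }
    m <- min(d)
    label[nodes[j]] <- fac[d == m][1L]  # fac already lex-sorted
    dist[nodes[j]] <- m
  }
  list(label = label, dist = dist, unreachable = unreachable)
}

# Minimum-cost facility over an explicit candidate set, computed from
# igraph distances only (no package ranking code).
argmin_candidate <- function(net, weights, candidates, demand_node, fs) {
  g <- as_igraph(net, weights)
  anchors <- fs$anchor_node[match(candidates, fs$facility_id)]
  d <- igraph::distances(g, v = demand_node, to = unique(anchors),
                         weights = igraph::E(g)$weight)[1, ]
  cost <- d[match(anchors, unique(anchors))]
  ord <- order(cost, candidates, method = "radix")
  list(facility_id = candidates[ord[1]], travel_time_s = unname(cost[ord[1]]))
}

# Exhaustive cheapest simple path between two nodes (tiny graphs only).
brute_force_cost <- function(net, weights, from, to) {
  if (from == to) return(0)
  g <- as_igraph(net)
  paths <- igraph::all_simple_paths(g, from = from, to = to)
  best <- Inf
  e <- net$edges
  for (p in paths) {
    ids <- names(p)
    cost <- 0
    for (i in seq_len(length(ids) - 1L)) {
      hit <- which((e$u == ids[i] & e$v == ids[i + 1L]) |
                     (e$v == ids[i] & e$u == ids[i + 1L]))
      cost <- cost + min(weights[e$edge_id[hit]])
    }
    best <- min(best, cost)
  }
  best
}

# Abstract (coordinate-free) network from an edge table; speeds default.
abstract_net <- function(edges, speed = 36) {
  ids <- sort(unique(c(edges$u, edges$v)), method = "radix")
  nodes <- data.frame(node_id = ids, lon = NA_real_, lat = NA_real_)
  if (!"edge_id" %in% names(edges)) {
    edges$edge_id <- paste0("e", seq_len(nrow(edges)))
  }
  if (!"speed_limit_kmh" %in% names(edges)) edges$speed_limit_kmh <- speed
  road_network(nodes, edges)
}

# Facility set anchored directly at named nodes (no snapping).
anchored_facilities <- function(anchor_nodes, available = 1L) {
  facility_set(data.frame(
    facility_id = names(anchor_nodes),
    name = names(anchor_nodes),
    lon = 0, lat = 0,
    available = rep_len(available, length(anchor_nodes)),
    anchor_node = unname(anchor_nodes),
    stringsAsFactors = FALSE))
}

# Hand-built catchment adjacency graph for candidate-set tests.
manual_adjacency <- function(neighbors) {
  structure(list(neighbors = neighbors, boundary_edges = character(0)),
            class = "catchment_adjacency")
}
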