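# Network Voronoi diagram: label every node with its nearest facility under
# a chosen per-edge cost, via one multi-source Dijkstra sweep.

# Compressed adjacency of the undirected graph: for node index i, neighbors
# are nbr[ptr[i]:(ptr[i+1]-1)] with edge costs wgt[...]. Both directions of
# each edge are materialized.
build_csr <- function(net, weights) {
  ids <- net$nodes$node_id
  n <- length(ids)
  ui <- match(net$edges$u, ids)
  vi <- match(net$edges$v, ids)
  w <- unname(weights[net$edges$edge_id])
  if (anyNA(w)) stop("weights must cover every edge_id", call. = FALSE)
  if (any(!is.finite(w) | w <= 0)) {
    stop("all edge weights must be positive and finite", call. = FALSE)
  }
  from <- c(ui, vi)
  to <- c(vi, ui)
  ww <- c(w, w)
  eid <- c(seq_len(nrow(net$edges)), seq_len(nrow(net$edges)))
  ord <- order(from)
  list(ids = ids, n = n,
       ptr = c(0L, cumsum(tabulate(from, n))) + 1L,
       nbr = to[ord], wgt = ww[ord], eidx = eid[ord])
}

# One Dijkstra sweep seeded at every source simultaneously. Returns the
# distance to the nearest source and, per node, the lexicographically
# smallest source label among all sources attaining that distance. Labels
# are resolved in a second pass over the shortest-path DAG (edges with
# dist[u] + w == dist[v]), processed in order of increasing distance, which
# reproduces exactly the per-source argmin-with-ties rule.
multi_source_dijkstra <- function(csr, source_idx, source_rank) {
  n <- csr$n
  dist <- rep(Inf, n)
  # a node hosting several sources starts with the best (smallest) rank
  seed_rank <- rep(NA_integer_, n)
  for (k in seq_along(source_idx)) {
    i <- source_idx[k]
    dist[i] <- 0
    if (is.na(seed_rank[i]) || source_rank[k] < seed_rank[i]) {
      seed_rank[i] <- source_rank[k]
    }
  }
  active <- dist  # Inf once settled
  repeat {
    u <- which.min(active)
    if (!is.finite(active[u])) break
    active[u] <- Inf
    lo <- csr$ptr[u]
    hi <- csr$ptr[u + 1L] - 1L
    if (hi >= lo) {
      idx <- lo:hi
      v <- csr$nbr[idx]
      nd <- dist[u] + csr$wgt[idx]
      upd <- nd < dist[v]
      if (any(upd)) {
        vv <- v[upd]
        dist[vv] <- nd[upd]
        active[vv] <- nd[upd]
      }
    }
  }
  lab <- seed_rank
  ord <- order(dist)
  for (u in ord) {
    if (!is.finite(dist[u])) break
    lo <- csr$ptr[u]
    hi <- csr$ptr[u + 1L] - 1L
    if (hi >= lo) {
      idx <- lo:hi
      v <- csr$nbr[idx]
      tight <- which(dist[v] + csr$wgt[idx] == dist[u])
      for (t in tight) {
        lv <- lab[v[t]]
        if (!is.na(lv) && (is.na(lab[u]) || lv < lab[u])) lab[u] <- lv
      }
    }
  }
  list(dist = dist, label = lab)
}

#' Build the network Voronoi diagram (catchment assignment)
#'
#' Assigns every reachable node of the road network to its nearest facility
#' by shortest-path cost under the supplied edge weights (meters for a
#' distance diagram, seconds for a time-based one). The assignment is
#' computed with a single multi-source Dijkstra sweep seeded at all facility
#' anchor nodes; a node equidistant from several facilities goes to the
#' lexicographically smallest `facility_id`. Nodes in components containing
#' no facility are reported as `unreachable`.
#'
#' @param net A [road_network()].
#' @param fs A [facility_set()] with anchors set (see [snap_facilities()]).
#' @param weights Named numeric per-edge cost vector (see [time_weights()],
#'   [distance_weights()]); all costs must be positive.
#' @param weight_kind Label recording what the costs mean, `"time_s"` or
#'   `"distance_m"`.
#' @param active_only If `TRUE`, facilities with `available == 0` are
#'   excluded as generators. The default keeps all generators and leaves
#'   availability to dispatch time.
#' @return An object of class `catchment_assignment`: named `label`
#'   (node -> facility_id), named `dist` (node -> cost to its facility),
#'   `unreachable` (character vector of node ids), `weight_kind`, and the
#'   generator table used.
#' @export
build_nvd <- function(net, fs, weights,
                      weight_kind = c("time_s", "distance_m"),
                      active_only = FALSE) {
  stopifnot(inherits(net, "road_network"), inherits(fs, "facility_set"))
  weight_kind <- match.arg(weight_kind)
  gen <- as.data.frame(fs)
  if (active_only) gen <- gen[gen$available == 1L, , drop = FALSE]
  if (nrow(gen) == 0L) {
    stop("no facilities to use as generators", call. = FALSE)
  }
  if (anyNA(gen$anchor_node)) {
    stop("facilities must be snapped to anchor nodes first", call. = FALSE)
  }
  fac_ids <- lex_sort(gen$facility_id)
  csr <- build_csr(net, weights)
  src_idx <- match(gen$anchor_node[match(fac_ids, gen$facility_id)], csr$ids)
  if (anyNA(src_idx)) {
    stop("facility anchor node missing from the network", call. = FALSE)
  }
  res <- multi_source_dijkstra(csr, src_idx, seq_along(fac_ids))
  reachable <- is.finite(res$dist)
  label <- setNames(fac_ids[res$label[reachable]], csr$ids[reachable])
  dist <- setNames(res$dist[reachable], csr$ids[reachable])
  structure(
    list(label = label, dist = dist,
         unreachable = csr$ids[!reachable],
         weight_kind = weight_kind,
         facilities = gen[match(fac_ids, gen$facility_id),
                          c("facility_id", "anchor_node", "available")]),
    class = "catchment_assignment"
  )
}

#' @export
print.catchment_assignment <- function(x, ...) {
  cat(sprintf("<catchment_assignment> %d nodes over %d facilities (%s); %d unreachable\n",
              length(x$label), nrow(x$facilities), x$weight_kind,
              length(x$unreachable)))
  invisible(x)
}

#' Catchment adjacency graph
#'
#' Two catchments are adjacent when at least one road segment joins a node
#' of one to a node of the other. Those segments are the boundary edges of
#' the network Voronoi diagram and the fallback search space for dispatch
#' when a home facility has no available unit.
#'
#' @param net The [road_network()] the assignment was built on.
#' @param ca A [build_nvd()] result.
#' @return An object of class `catchment_adjacency`: `neighbors`, a named
#'   list facility_id -> sorted character vector of adjacent facility ids,
#'   and `boundary_edges`, the edge ids crossing catchment boundaries.
#' @export
adjacency <- function(net, ca) {
  stopifnot(inherits(net, "road_network"), inherits(ca, "catchment_assignment"))
  lu <- ca$label[net$edges$u]
  lv <- ca$label[net$edges$v]
  cross <- !is.na(lu) & !is.na(lv) & lu != lv
  fac <- ca$facilities$facility_id
  neighbors <- setNames(lapply(fac, function(f) {
    lex_sort(unique(c(lv[cross & lu == f], lu[cross & lv == f])))
  }), fac)
  structure(
    list(neighbors = neighbors,
         boundary_edges = lex_sort(net$edges$edge_id[cross])),
    class = "catchment_adjacency"
  )
}

#' @export
print.catchment_adjacency <- function(x, ...) {
  deg <- vapply(x$neighbors, length, integer(1))
  cat(sprintf("<catchment_adjacency> %d catchments, %d boundary edges, mean degree %.1f\n",
              length(x$neighbors), length(x$boundary_edges), mean(deg)))
  invisible(x)
}

#' Look up the catchment of a node
#'
#' @param ca A [build_nvd()] result.
#' @param node A `node_id`.
#' @return The `facility_id` whose catchment contains the node.
#' @export
catchment_of <- function(ca, node) {
  stopifnot(inherits(ca, "catchment_assignment"))
  if (node %in% ca$unreachable) {
    stop("node ", node, " has no facility coverage (no facility in its ",
         "network component)", call. = FALSE)
  }
  f <- ca$label[node]
  if (is.na(f)) stop("unknown node: ", node, call. = FALSE)
  unname(f)
}

#' Export catchments to GeoJSON
#'
#' Writes one feature per facility containing its labeled nodes — as a
#' MultiPoint by default, or as a convex-hull Polygon when
#' `hull = TRUE` — plus the boundary edges as LineString features. A
#' facility whose catchment is empty (e.g. dominated everywhere after
#' sharing an anchor) is written with an empty geometry and flagged with a
#' warning.
#'
#' @param net The [road_network()].
#' @param ca A [build_nvd()] result.
#' @param path Output path.
#' @param hull Emit convex-hull polygons instead of MultiPoints.
#' @return `path`, invisibly.
#' @export
export_catchments <- function(net, ca, path, hull = FALSE) {
  stopifnot(inherits(ca, "catchment_assignment"))
  nd <- net$nodes
  feats <- lapply(ca$facilities$facility_id, function(f) {
    ids <- names(ca$label)[ca$label == f]
    pts <- nd[match(ids, nd$node_id), c("lon", "lat"), drop = FALSE]
    if (nrow(pts) == 0L) {
      warning("facility ", f, " has an empty catchment", call. = FALSE)
      geom <- list(type = "MultiPoint", coordinates = list())
    } else if (hull && nrow(pts) >= 3L) {
      h <- grDevices::chull(pts$lon, pts$lat)
      ring <- pts[c(h, h[1]), , drop = FALSE]
      geom <- list(type = "Polygon",
                   coordinates = list(unname(
                     lapply(seq_len(nrow(ring)),
                            function(i) c(ring$lon[i], ring$lat[i])))))
    } else {
      geom <- list(type = "MultiPoint",
                   coordinates = unname(lapply(seq_len(nrow(pts)),
                                               function(i) c(pts$lon[i], pts$lat[i]))))
    }
    list(type = "Feature",
         properties = list(kind = "catchment", facility_id = f,
                           node_count = length(ids)),
         geometry = geom)
  })
  adj <- adjacency(net, ca)
  bedges <- lapply(adj$boundary_edges, function(eid) {
    e <- net$edges[net$edges$edge_id == eid, ]
    i <- match(e$u, nd$node_id)
    j <- match(e$v, nd$node_id)
    list(type = "Feature",
         properties = list(kind = "boundary_edge", edge_id = eid,
                           from_facility = unname(ca$label[e$u]),
                           to_facility = unname(ca$label[e$v])),
         geometry = list(type = "LineString",
                         coordinates = list(c(nd$lon[i], nd$lat[i]),
                                            c(nd$lon[j], nd$lat[j]))))
  })
  write_json_stable(list(type = "FeatureCollection",
                         features = c(feats, bedges)), path)
  invisible(path)
}
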