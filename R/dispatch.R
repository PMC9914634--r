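# Four-phase unit selection: locate the demand's catchment, assemble the
# candidate facilities (home + adjacent, availability-aware, with ring
# expansion over the catchment adjacency graph), rank candidates by
# time-based shortest path, select the minimum.

#' Create a dispatch request
#'
#' @param lon,lat Demand (incident) coordinates, degrees; ignored when
#'   `node_id` is given.
#' @param node_id Optional demand node directly (skips snapping).
#' @param availability_override Optional named vector facility_id -> 0/1
#'   overriding the facility table's availability flags for this request.
#' @return An object of class `dispatch_request`.
#' @export
dispatch_request <- function(lon = NULL, lat = NULL, node_id = NULL,
                             availability_override = NULL) {
  if (is.null(node_id) && (is.null(lon) || is.null(lat))) {
    stop("supply either lon/lat or node_id", call. = FALSE)
  }
  if (!is.null(availability_override)) {
    if (is.null(names(availability_override)) ||
        !all(availability_override %in% c(0, 1))) {
      stop("availability_override must be a named vector of 0/1",
           call. = FALSE)
    }
  }
  structure(list(lon = lon, lat = lat, node_id = node_id,
                 availability_override = availability_override),
            class = "dispatch_request")
}

#' Phase 1: locate the demand node and its home catchment
#'
#' Snaps the request to the network (if given as coordinates) and returns
#' the facility whose catchment contains the demand node.
#'
#' @param ca A [build_nvd()] result.
#' @param request A [dispatch_request()].
#' @param net The [road_network()] the assignment was built on.
#' @return List with `demand_node` and `home_facility`.
#' @export
locate <- function(ca, request, net) {
  stopifnot(inherits(request, "dispatch_request"))
  node <- request$node_id %||% snap_point(net, request$lon, request$lat)
  if (!node %in% net$nodes$node_id) {
    stop_phase("locate", "unknown demand node: ", node)
  }
  if (node %in% ca$unreachable) {
    stop_phase("locate", "demand node ", node,
               " has no facility coverage (no facility in its component)")
  }
  list(demand_node = node, home_facility = catchment_of(ca, node))
}

#' Phase 2: assemble the candidate facility set
#'
#' If the home facility has an available unit, the candidates are the home
#' facility plus the available facilities in adjacent catchments. If the
#' home unit is out, the candidates are the available adjacent facilities
#' alone. If no adjacent facility is available either, the search expands
#' ring by ring over the catchment adjacency graph (neighbors of neighbors,
#' breadth-first) and stops at the first ring containing any available
#' facility. Only available facilities are ever returned: an unavailable
#' unit can never be dispatched.
#'
#' @param home The home `facility_id`.
#' @param adj A [adjacency()] result.
#' @param availability Named vector facility_id -> 0/1.
#' @return Sorted character vector of candidate facility ids.
#' @export
candidate_set <- function(home, adj, availability) {
  stopifnot(inherits(adj, "catchment_adjacency"))
  fac <- names(adj$neighbors)
  if (!home %in% fac) stop_phase("candidates", "unknown facility: ", home)
  if (!all(fac %in% names(availability))) {
    stop_phase("candidates", "availability must cover every facility")
  }
  avail <- function(ids) ids[availability[ids] == 1]
  ring <- unique(c(if (availability[home] == 1) home, adj$neighbors[[home]]))
  visited <- unique(c(home, adj$neighbors[[home]]))
  cand <- avail(ring)
  while (length(cand) == 0L) {
    nxt <- setdiff(unique(unlist(adj$neighbors[ring], use.names = FALSE)),
                   visited)
    if (length(nxt) == 0L) {
      stop_phase("candidates", "no available facility reachable through ",
                 "the catchment adjacency graph")
    }
    visited <- c(visited, nxt)
    ring <- nxt
    cand <- avail(ring)
  }
  lex_sort(cand)
}

#' Phase 3: rank candidate facilities by travel time
#'
#' Runs one Dijkstra rooted at the demand node under the given time weights
#' (the graph is undirected, so demand-to-facility cost equals
#' facility-to-demand cost) and sorts the candidates by ascending
#' `(travel_time_s, facility_id)`. Each candidate's reported time is the sum
#' of its route's edge weights. Candidates unreachable from the demand node
#' are dropped with a warning; if none remains, an error is raised.
#'
#' @param net A [road_network()].
#' @param weights Named per-edge cost vector (seconds).
#' @param candidates Character vector of facility ids to rank.
#' @param demand_node The demand `node_id`.
#' @param fs The [facility_set()] (for anchor lookup).
#' @param graph Optional pre-built `igraph` from
#'   `as_igraph(net, weights)`, reused across many requests.
#' @return Data frame with columns `facility_id`, `travel_time_s`, `path`
#'   (list column: node sequence from facility anchor to demand node).
#' @export
rank_candidates <- function(net, weights, candidates, demand_node, fs,
                            graph = NULL) {
  if (length(candidates) == 0L) {
    stop_phase("rank", "empty candidate set")
  }
  g <- graph %||% as_igraph(net, weights)
  anchors <- fs$anchor_node[match(candidates, fs$facility_id)]
  if (anyNA(anchors)) stop_phase("rank", "candidate facility not in facility set")
  sp <- suppressWarnings(
    igraph::shortest_paths(g, from = demand_node, to = unique(anchors),
                           weights = igraph::E(g)$weight,
                           output = "both"))
  names(sp$vpath) <- unique(anchors)
  names(sp$epath) <- unique(anchors)
  rows <- lapply(seq_along(candidates), function(i) {
    a <- anchors[i]
    vp <- sp$vpath[[a]]
    if (length(vp) == 0L && a != demand_node) return(NULL)  # unreachable
    ep <- sp$epath[[a]]
    tt <- if (length(ep)) sum(igraph::E(g)$weight[as.integer(ep)]) else 0
    path <- rev(names(vp))  # facility anchor -> demand node
    if (length(path) == 0L) path <- demand_node
    list(facility_id = candidates[i], travel_time_s = tt, path = path)
  })
  drop <- vapply(rows, is.null, logical(1))
  if (any(drop)) {
    warning("candidate(s) unreachable from demand node: ",
            paste(candidates[drop], collapse = ", "), call. = FALSE)
    rows <- rows[!drop]
  }
  if (length(rows) == 0L) {
    stop_phase("rank", "no candidate reachable from demand node ", demand_node)
  }
  out <- data.frame(
    facility_id = vapply(rows, `[[`, character(1), "facility_id"),
    travel_time_s = vapply(rows, `[[`, numeric(1), "travel_time_s"),
    stringsAsFactors = FALSE)
  out$path <- lapply(rows, `[[`, "path")
  out <- out[order(out$travel_time_s, out$facility_id, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Dispatch the best available unit to a demand point
#'
#' Composes the four phases — locate, candidate assembly, time-based
#' ranking, selection — and records each phase in an audit log. Ties in the
#' final selection fall to the lexicographically smallest facility id (the
#' ranking already sorts by `(time, facility_id)`).
#'
#' @param net A [road_network()].
#' @param fs A snapped [facility_set()].
#' @param ca A [build_nvd()] result for `net`/`fs`.
#' @param adj The matching [adjacency()] result.
#' @param weights Named per-edge time cost vector used for ranking.
#' @param request A [dispatch_request()].
#' @param graph Optional pre-built `igraph` (see [rank_candidates()]).
#' @return An object of class `dispatch_result`: `selected` (one-row data
#'   frame with facility, time, path and whether it came from the home or an
#'   adjacent catchment), `ranked` (all candidates), `demand_node`,
#'   `home_facility` and `phase_log`.
#' @export
dispatch <- function(net, fs, ca, adj, weights, request, graph = NULL) {
  stopifnot(inherits(fs, "facility_set"))
  loc <- locate(ca, request, net)
  availability <- setNames(as.numeric(fs$available), fs$facility_id)
  ov <- request$availability_override
  if (!is.null(ov)) availability[names(ov)] <- as.numeric(ov)
  cand <- candidate_set(loc$home_facility, adj, availability)
  ranked <- rank_candidates(net, weights, cand, loc$demand_node, fs, graph)
  ranked$source <- ifelse(ranked$facility_id == loc$home_facility,
                          "home_catchment", "adjacent_catchment")
  selected <- ranked[1L, , drop = FALSE]
  phase_log <- list(
    list(phase = "locate", demand_node = loc$demand_node,
         home_facility = loc$home_facility),
    list(phase = "candidates", home_available = unname(availability[loc$home_facility]),
         candidates = as.list(cand)),
    list(phase = "rank",
         order = as.list(ranked$facility_id),
         travel_time_s = as.list(ranked$travel_time_s)),
    list(phase = "select", facility_id = selected$facility_id,
         travel_time_s = selected$travel_time_s,
         source = selected$source)
  )
  structure(list(selected = selected, ranked = ranked,
                 demand_node = loc$demand_node,
                 home_facility = loc$home_facility,
                 phase_log = phase_log),
            class = "dispatch_result")
}

#' @export
print.dispatch_result <- function(x, ...) {
  cat(sprintf("<dispatch_result> demand %s (home %s) -> %s (%.1f s, %s; %d candidates)\n",
              x$demand_node, x$home_facility, x$selected$facility_id,
              x$selected$travel_time_s, x$selected$source, nrow(x$ranked)))
  invisible(x)
}

#' Length- and time-based costs of a route
#'
#' For a node sequence along the network, returns the summed edge lengths
#' (the cost a classical length-only Dijkstra minimizes) and the summed
#' congestion-adjusted travel times under both formula modes, enabling
#' side-by-side comparison of distance-based and time-based route costs.
#' Where parallel edges join two consecutive nodes, the one with the
#' smallest division-mode travel time (ties: smallest edge id) is charged.
#'
#' @param net A [road_network()].
#' @param path Character vector of consecutive, adjacent node ids; a path of
#'   length <= 1 has zero cost.
#' @param clamp_max Saturation clamp for the time computation.
#' @param saturation_override Optional constant saturation applied to all
#'   edges (e.g. a 0.70 scenario).
#' @return List with `distance_m`, `time_s_division`, `time_s_printed`,
#'   `time_s_free` and the charged `edge_ids`.
#' @export
route_costs <- function(net, path, clamp_max = 0.95,
                        saturation_override = NULL) {
  stopifnot(inherits(net, "road_network"))
  if (length(path) <= 1L) {
    return(list(distance_m = 0, time_s_division = 0, time_s_printed = 0,
                time_s_free = 0, edge_ids = character(0)))
  }
  ew_div <- weight_all_edges(net, "greenshields_division", clamp_max,
                             saturation_override)
  ew_prt <- weight_all_edges(net, "as_printed", clamp_max,
                             saturation_override)
  e <- net$edges
  pick <- vapply(seq_len(length(path) - 1L), function(i) {
    a <- path[i]; b <- path[i + 1L]
    hit <- which((e$u == a & e$v == b) | (e$u == b & e$v == a))
    if (length(hit) == 0L) {
      stop("nodes ", a, " and ", b, " are not joined by an edge",
           call. = FALSE)
    }
    if (length(hit) > 1L) {
      ord <- order(ew_div$t_travel_s[hit], e$edge_id[hit], method = "radix")
      hit <- hit[ord]
    }
    hit[1L]
  }, integer(1))
  list(distance_m = sum(e$length_m[pick]),
       time_s_division = sum(ew_div$t_travel_s[pick]),
       time_s_printed = sum(ew_prt$t_travel_s[pick]),
       time_s_free = sum(ew_div$t_free_s[pick]),
       edge_ids = e$edge_id[pick])
}
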