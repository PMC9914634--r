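#' Construct a road network
#'
#' A road network is a weighted undirected graph: nodes with WGS84
#' coordinates and road segments (edges) carrying the attributes the
#' travel-time model needs — length in meters, a speed limit in km/h, the
#' number of vehicles currently occupying the segment, and the segment's
#' maximum (jam) traffic density. Segments without a posted speed limit are
#' assigned the configured default (40 km/h unless overridden) and marked
#' `speed_source = "default"`; missing vehicle counts default to 0 (free
#' flow) and missing jam densities to the configured `default_k_max`.
#'
#' @param nodes Data frame with columns `node_id`, `lon`, `lat`. Coordinates
#'   may be `NA` (e.g. for abstract test graphs); such nodes cannot be used
#'   for snapping.
#' @param edges Data frame with columns `edge_id`, `u`, `v`, `length_m`, and
#'   optionally `speed_limit_kmh` (or `speed_kmh`), `vehicle_count`, `k_max`.
#' @param config An [app_config()] supplying defaults.
#'
#' @return An object of class `road_network`: a list with validated `nodes`
#'   and `edges` data frames.
#' @examples
#' nodes <- data.frame(node_id = c("a", "b"), lon = c(0, 0.01), lat = 0)
#' edges <- data.frame(edge_id = "e1", u = "a", v = "b", length_m = 1100)
#' net <- road_network(nodes, edges)
#' net$edges$speed_limit_kmh  # default 40, speed_source "default"
#' @export
road_network <- function(nodes, edges, config = app_config()) {
  stopifnot(is.data.frame(nodes), is.data.frame(edges))
  need_n <- c("node_id", "lon", "lat")
  if (!all(need_n %in% names(nodes))) {
    stop("nodes must have columns: ", paste(need_n, collapse = ", "),
         call. = FALSE)
  }
  if ("speed_kmh" %in% names(edges) && !"speed_limit_kmh" %in% names(edges)) {
    names(edges)[names(edges) == "speed_kmh"] <- "speed_limit_kmh"
  }
  need_e <- c("edge_id", "u", "v", "length_m")
  if (!all(need_e %in% names(edges))) {
    stop("edges must have columns: ", paste(need_e, collapse = ", "),
         call. = FALSE)
  }
  nodes <- data.frame(node_id = as.character(nodes$node_id),
                      lon = as.numeric(nodes$lon),
                      lat = as.numeric(nodes$lat),
                      stringsAsFactors = FALSE)
  if (anyDuplicated(nodes$node_id)) {
    dup <- nodes$node_id[duplicated(nodes$node_id)][1L]
    stop("duplicate node_id: ", dup, call. = FALSE)
  }
  ok_lon <- is.na(nodes$lon) | (nodes$lon >= -180 & nodes$lon <= 180)
  ok_lat <- is.na(nodes$lat) | (nodes$lat >= -90 & nodes$lat <= 90)
  if (!all(ok_lon & ok_lat)) {
    bad <- nodes$node_id[!(ok_lon & ok_lat)][1L]
    stop("node ", bad, ": coordinates outside WGS84 bounds", call. = FALSE)
  }

  n_e <- nrow(edges)
  has_speed <- "speed_limit_kmh" %in% names(edges)
  speed <- if (has_speed) as.numeric(edges$speed_limit_kmh) else rep(NA_real_, n_e)
  speed_source <- ifelse(is.na(speed), "default", "given")
  speed[is.na(speed)] <- config$default_speed_kmh
  vc <- if ("vehicle_count" %in% names(edges)) as.numeric(edges$vehicle_count) else rep(NA_real_, n_e)
  vc[is.na(vc)] <- 0
  kmax <- if ("k_max" %in% names(edges)) as.numeric(edges$k_max) else rep(NA_real_, n_e)
  kmax[is.na(kmax)] <- config$default_k_max
  if ("speed_source" %in% names(edges)) speed_source <- as.character(edges$speed_source)

  edges <- data.frame(edge_id = as.character(edges$edge_id),
                      u = as.character(edges$u),
                      v = as.character(edges$v),
                      length_m = as.numeric(edges$length_m),
                      speed_limit_kmh = speed,
                      vehicle_count = vc,
                      k_max = kmax,
                      speed_source = speed_source,
                      stringsAsFactors = FALSE)
  if (anyDuplicated(edges$edge_id)) {
    dup <- edges$edge_id[duplicated(edges$edge_id)][1L]
    stop("duplicate edge_id: ", dup, call. = FALSE)
  }
  check_pos <- function(x, what) {
    bad <- which(!is.finite(x) | x <= 0)
    if (length(bad)) {
      stop("edge ", edges$edge_id[bad[1L]], ": ", what, " must be > 0",
           call. = FALSE)
    }
  }
  check_pos(edges$length_m, "length_m")
  check_pos(edges$speed_limit_kmh, "speed_limit_kmh")
  check_pos(edges$k_max, "k_max")
  if (any(edges$vehicle_count < 0)) {
    bad <- edges$edge_id[which(edges$vehicle_count < 0)[1L]]
    stop("edge ", bad, ": vehicle_count must be >= 0", call. = FALSE)
  }
  if (any(edges$u == edges$v)) {
    bad <- edges$edge_id[which(edges$u == edges$v)[1L]]
    stop("edge ", bad, ": self-loops are not accepted", call. = FALSE)
  }
  missing_ep <- setdiff(c(edges$u, edges$v), nodes$node_id)
  if (length(missing_ep)) {
    stop("edge endpoint not in node set: ", missing_ep[1L], call. = FALSE)
  }
  structure(list(nodes = nodes, edges = edges), class = "road_network")
}

#' @export
print.road_network <- function(x, ...) {
  cat(sprintf("<road_network> %d nodes, %d edges (undirected)\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Read a road network from disk
#'
#' Two dialects are supported. `edge_csv` is a comma-separated edge list with
#' header `edge_id,u,v,length_m,speed_kmh,vehicle_count,k_max`; the last
#' three columns may be empty or absent entirely, and a missing `edge_id`
#' column is synthesized as `e1, e2, ...` in file order. Because an edge list
#' carries no geometry, node coordinates are read from a companion nodes CSV
#' (`node_id,lon,lat`) when `nodes_path` is given, and are `NA` otherwise.
#' `geojson_lines` is a FeatureCollection of LineString features with
#' properties `length_m` (computed from the geometry as the summed
#' great-circle length of its segments when absent), `speed_kmh`,
#' `vehicle_count` and `k_max`; nodes are the deduplicated LineString
#' endpoints, matched at 1e-7 degrees.
#'
#' @param path Path to the network file.
#' @param format `"edge_csv"` or `"geojson_lines"`.
#' @param config An [app_config()]; supplies the default speed for edges
#'   with an empty speed column.
#' @param nodes_path Optional path to a `node_id,lon,lat` CSV
#'   (edge_csv format only).
#' @return A validated [road_network()].
#' @export
read_network <- function(path, format = c("edge_csv", "geojson_lines"),
                         config = app_config(), nodes_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "edge_csv") {
    read_network_csv(path, config, nodes_path)
  } else {
    read_network_geojson(path, config)
  }
}

read_network_csv <- function(path, config, nodes_path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = "character", check.names = TRUE)
  need <- c("u", "v", "length_m")
  if (!all(need %in% names(df))) {
    stop("edge_csv at ", path, " is missing required column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  }
  if (!"edge_id" %in% names(df)) df$edge_id <- paste0("e", seq_len(nrow(df)))
  num <- function(x) suppressWarnings(as.numeric(ifelse(x == "", NA, x)))
  edges <- data.frame(edge_id = df$edge_id, u = df$u, v = df$v,
                      length_m = num(df$length_m),
                      stringsAsFactors = FALSE)
  bad_len <- which(is.na(edges$length_m))
  if (length(bad_len)) {
    stop("edge_csv record ", edges$edge_id[bad_len[1L]],
         ": length_m is not a number", call. = FALSE)
  }
  if ("speed_kmh" %in% names(df)) edges$speed_limit_kmh <- num(df$speed_kmh)
  if ("vehicle_count" %in% names(df)) edges$vehicle_count <- num(df$vehicle_count)
  if ("k_max" %in% names(df)) edges$k_max <- num(df$k_max)

  ids <- lex_sort(unique(c(edges$u, edges$v)))
  nodes <- data.frame(node_id = ids, lon = NA_real_, lat = NA_real_,
                      stringsAsFactors = FALSE)
  if (!is.null(nodes_path)) {
    nd <- read.csv(nodes_path, stringsAsFactors = FALSE)
    if (!all(c("node_id", "lon", "lat") %in% names(nd))) {
      stop("nodes CSV must have columns node_id,lon,lat", call. = FALSE)
    }
    nd$node_id <- as.character(nd$node_id)
    i <- match(nodes$node_id, nd$node_id)
    nodes$lon <- nd$lon[i]
    nodes$lat <- nd$lat[i]
    extra <- setdiff(nd$node_id, nodes$node_id)
    if (length(extra)) {
      nodes <- rbind(nodes,
                     data.frame(node_id = extra,
                                lon = nd$lon[match(extra, nd$node_id)],
                                lat = nd$lat[match(extra, nd$node_id)],
                                stringsAsFactors = FALSE))
    }
  }
  road_network(nodes, edges, config)
}

read_network_geojson <- function(path, config) {
  gj <- jsonlite::read_json(path)
  if (!identical(gj$type, "FeatureCollection")) {
    stop("geojson_lines: expected a FeatureCollection in ", path,
         call. = FALSE)
  }
  key_of <- function(lon, lat) {
    # endpoint deduplication at 1e-7 degrees
    sprintf("%.7f,%.7f", round(lon, 7), round(lat, 7))
  }
  node_env <- new.env(parent = emptyenv())
  node_rows <- list()
  get_node <- function(lon, lat) {
    k <- key_of(lon, lat)
    if (!is.null(node_env[[k]])) return(node_env[[k]])
    id <- sprintf("n%d", length(node_rows) + 1L)
    node_env[[k]] <- id
    node_rows[[id]] <<- c(lon, lat)
    id
  }
  edges <- vector("list", length(gj$features))
  for (i in seq_along(gj$features)) {
    f <- gj$features[[i]]
    geom <- f$geometry
    if (is.null(geom) || !identical(geom$type, "LineString")) {
      stop("geojson_lines feature ", i, ": geometry must be a LineString",
           call. = FALSE)
    }
    coords <- geom$coordinates
    if (length(coords) < 2L) {
      stop("geojson_lines feature ", i, ": LineString needs >= 2 coordinates",
           call. = FALSE)
    }
    pts <- do.call(rbind, lapply(coords, function(c2) {
      as.numeric(c2[1:2])
    }))
    props <- f$properties %||% list()
    len <- props$length_m
    if (is.null(len)) {
      segs <- geosphere::distHaversine(pts[-nrow(pts), , drop = FALSE],
                                       pts[-1, , drop = FALSE])
      len <- sum(segs)
    }
    u <- get_node(pts[1, 1], pts[1, 2])
    v <- get_node(pts[nrow(pts), 1], pts[nrow(pts), 2])
    edges[[i]] <- data.frame(
      edge_id = as.character(props$edge_id %||% sprintf("e%d", i)),
      u = u, v = v, length_m = as.numeric(len),
      speed_limit_kmh = as.numeric(props$speed_kmh %||% NA_real_),
      vehicle_count = as.numeric(props$vehicle_count %||% NA_real_),
      k_max = as.numeric(props$k_max %||% NA_real_),
      stringsAsFactors = FALSE)
  }
  edges <- do.call(rbind, edges)
  nodes <- data.frame(node_id = names(node_rows),
                      lon = vapply(node_rows, `[`, numeric(1), 1L),
                      lat = vapply(node_rows, `[`, numeric(1), 2L),
                      stringsAsFactors = FALSE)
  road_network(nodes, edges, config)
}

#' Write a road network to disk
#'
#' Inverse of [read_network()]. For `edge_csv` the full dialect header is
#' written; a companion nodes CSV is written when `nodes_path` is given. For
#' `geojson_lines` each edge becomes a two-point LineString between its node
#' coordinates, with all traffic attributes as properties.
#'
#' @inheritParams read_network
#' @param net A [road_network()].
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("edge_csv", "geojson_lines"),
                          nodes_path = NULL) {
  stopifnot(inherits(net, "road_network"))
  format <- match.arg(format)
  if (format == "edge_csv") {
    e <- net$edges
    out <- data.frame(edge_id = e$edge_id, u = e$u, v = e$v,
                      length_m = e$length_m,
                      speed_kmh = ifelse(e$speed_source == "default", "",
                                         as.character(e$speed_limit_kmh)),
                      vehicle_count = e$vehicle_count,
                      k_max = e$k_max,
                      stringsAsFactors = FALSE)
    write.csv(out, path, row.names = FALSE, quote = FALSE)
    if (!is.null(nodes_path)) {
      write.csv(net$nodes, nodes_path, row.names = FALSE, quote = FALSE)
    }
  } else {
    ni <- match(net$edges$u, net$nodes$node_id)
    nj <- match(net$edges$v, net$nodes$node_id)
    feats <- lapply(seq_len(nrow(net$edges)), function(i) {
      e <- net$edges[i, ]
      props <- list(edge_id = e$edge_id, length_m = e$length_m,
                    vehicle_count = e$vehicle_count, k_max = e$k_max)
      if (e$speed_source == "given") props$speed_kmh <- e$speed_limit_kmh
      list(type = "Feature",
           properties = props,
           geometry = list(
             type = "LineString",
             coordinates = list(
               c(net$nodes$lon[ni[i]], net$nodes$lat[ni[i]]),
               c(net$nodes$lon[nj[i]], net$nodes$lat[nj[i]]))))
    })
    write_json_stable(list(type = "FeatureCollection", features = feats), path)
  }
  invisible(path)
}

#' Snap a coordinate to the nearest network node
#'
#' Returns the node minimizing great-circle (haversine) distance to the
#' query point; exact distance ties are broken by the lexicographically
#' smallest `node_id`. Geometry is used only here — routing always follows
#' edge lengths, never straight-line node distances.
#'
#' @param net A [road_network()] whose nodes carry coordinates.
#' @param lon,lat Query point, degrees WGS84.
#' @return A `node_id`.
#' @export
snap_point <- function(net, lon, lat) {
  stopifnot(inherits(net, "road_network"))
  nd <- net$nodes[is.finite(net$nodes$lon) & is.finite(net$nodes$lat), ]
  if (nrow(nd) == 0L) {
    stop("network has no nodes with coordinates to snap to", call. = FALSE)
  }
  d <- haversine_m(lon, lat, nd$lon, nd$lat)
  lex_min(nd$node_id[d == min(d)])
}

#' Anchor facilities to network nodes
#'
#' Sets each facility's `anchor_node` to its nearest network node via
#' [snap_point()]. The generator set of the network Voronoi diagram must be
#' a subset of the graph nodes, so all catchment and dispatch logic operates
#' on anchors. Two facilities may legitimately share an anchor (e.g. two
#' stations on the same block); this is allowed but flagged with a warning.
#'
#' @param net A [road_network()].
#' @param fs A [facility_set()].
#' @return The facility set with `anchor_node` filled in.
#' @export
snap_facilities <- function(net, fs) {
  stopifnot(inherits(fs, "facility_set"))
  fs$anchor_node <- vapply(seq_len(nrow(fs)), function(i) {
    snap_point(net, fs$lon[i], fs$lat[i])
  }, character(1))
  dup <- unique(fs$anchor_node[duplicated(fs$anchor_node)])
  if (length(dup)) {
    warning("facilities share anchor node(s): ", paste(dup, collapse = ", "),
            call. = FALSE)
  }
  fs
}

#' Connected components of the road network
#'
#' @param net A [road_network()].
#' @return A list of character vectors of `node_id`s, one per component,
#'   each sorted lexicographically; components ordered by their smallest
#'   member. Isolated nodes form singleton components.
#' @export
connected_components <- function(net) {
  g <- as_igraph(net)
  memb <- igraph::components(g)$membership
  comps <- split(names(memb), memb)
  comps <- lapply(comps, lex_sort)
  names(comps) <- NULL
  comps[lex_order(vapply(comps, `[`, character(1), 1L))]
}

#' Convert a road network to an igraph graph
#'
#' Vertices are node ids; edges keep `edge_id` and `length_m` attributes and
#' optionally a `weight` attribute from a named cost vector.
#'
#' @param net A [road_network()].
#' @param weights Optional named numeric vector of per-edge costs, names
#'   being `edge_id`s (e.g. the `t_travel_s` column of [weight_all_edges()]).
#' @return An undirected `igraph` graph.
#' @export
as_igraph <- function(net, weights = NULL) {
  stopifnot(inherits(net, "road_network"))
  e <- data.frame(from = net$edges$u, to = net$edges$v,
                  edge_id = net$edges$edge_id,
                  length_m = net$edges$length_m,
                  stringsAsFactors = FALSE)
  if (!is.null(weights)) {
    w <- unname(weights[net$edges$edge_id])
    if (anyNA(w)) stop("weights must cover every edge_id", call. = FALSE)
    if (any(w <= 0)) stop("edge weights must be positive", call. = FALSE)
    e$weight <- w
  }
  igraph::graph_from_data_frame(e, directed = FALSE,
                                vertices = net$nodes$node_id)
}

#' Construct a facility set
#'
#' Facilities are the EMS stations that act as generators of the network
#' Voronoi diagram. Each carries an availability flag (1 = an ambulance is
#' stationed and free, 0 = not) consulted at dispatch time.
#'
#' @param df Data frame with columns `facility_id`, `lon`, `lat` and
#'   optionally `name`, `available` (default 1) and `anchor_node`.
#' @return A data frame of class `facility_set`.
#' @export
facility_set <- function(df) {
  stopifnot(is.data.frame(df))
  if (!all(c("facility_id", "lon", "lat") %in% names(df))) {
    stop("facilities need columns facility_id, lon, lat", call. = FALSE)
  }
  if (nrow(df) < 1L) stop("at least one facility is required", call. = FALSE)
  out <- data.frame(facility_id = as.character(df$facility_id),
                    name = as.character(df$name %||% df$facility_id),
                    lon = as.numeric(df$lon),
                    lat = as.numeric(df$lat),
                    available = as.integer(df$available %||% 1L),
                    anchor_node = as.character(df$anchor_node %||% NA_character_),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$facility_id)) {
    stop("duplicate facility_id: ",
         out$facility_id[duplicated(out$facility_id)][1L], call. = FALSE)
  }
  if (!all(out$available %in% c(0L, 1L))) {
    stop("available must be 0 or 1", call. = FALSE)
  }
  class(out) <- c("facility_set", "data.frame")
  out
}

#' Read or write a facility table
#'
#' CSV dialect: `facility_id,name,lon,lat,available`. GeoJSON dialect: Point
#' features with the same fields as properties.
#'
#' @param path File path; format inferred from the extension (`.csv` vs
#'   `.geojson`/`.json`) unless given.
#' @param format `"csv"` or `"geojson_points"`.
#' @return A [facility_set()].
#' @export
read_facilities <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "geojson_points"
  }
  if (format == "csv") {
    facility_set(read.csv(path, stringsAsFactors = FALSE))
  } else {
    gj <- jsonlite::read_json(path)
    rows <- lapply(gj$features, function(f) {
      p <- f$properties %||% list()
      data.frame(facility_id = as.character(p$facility_id),
                 name = as.character(p$name %||% p$facility_id),
                 lon = as.numeric(f$geometry$coordinates[[1]]),
                 lat = as.numeric(f$geometry$coordinates[[2]]),
                 available = as.integer(p$available %||% 1L),
                 stringsAsFactors = FALSE)
    })
    facility_set(do.call(rbind, rows))
  }
}

#' @rdname read_facilities
#' @param fs A [facility_set()].
#' @export
write_facilities <- function(fs, path) {
  stopifnot(inherits(fs, "facility_set"))
  write.csv(fs[, c("facility_id", "name", "lon", "lat", "available")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
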