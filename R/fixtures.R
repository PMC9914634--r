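# Seeded synthetic road networks, facilities and demand points. Everything
# every other module needs for testing is generated here in code; no
# downloaded map data is required.

M_PER_DEG_LAT <- 111320

offset_lonlat <- function(lon0, lat0, dx_m, dy_m) {
  cbind(lon = lon0 + dx_m / (M_PER_DEG_LAT * cos(lat0 * pi / 180)),
        lat = lat0 + dy_m / M_PER_DEG_LAT)
}

#' Specify a synthetic fixture
#'
#' Describes a deterministic synthetic scenario: a road network of the given
#' shape, a set of facilities placed at distinct nodes, and a sample of
#' demand points. The seed fully determines the output.
#'
#' @param kind `"grid"`, `"random_planar"`, `"path"` or `"star"`.
#' @param rows,cols Grid dimensions (grid kind).
#' @param node_count Node count (random_planar, path, star kinds; for star
#'   this is hub + leaves).
#' @param edge_length_m Edge length in meters for regular shapes (grid,
#'   path, star). Random planar edges take their haversine length.
#' @param speed_set Speed limits (km/h) sampled uniformly per edge.
#' @param missing_speed_frac Fraction of edges left without a speed limit,
#'   exercising the default-speed substitution.
#' @param congestion Either `NULL` (free flow), a single saturation ratio
#'   applied to every edge, or `c(min, max)` sampled uniformly per edge.
#'   Vehicle counts are derived so each edge's density/k_max equals the
#'   drawn ratio exactly.
#' @param k_max Maximum density (veh/km) stamped on every edge.
#' @param facility_count Number of facilities, placed at distinct nodes.
#' @param demand_count Number of demand points, drawn at nodes with a small
#'   (10 m) jitter.
#' @param seed Integer seed.
#' @param allow_disconnected Skip the connectivity repair step
#'   (random_planar only).
#' @param origin Lon/lat of the fixture's local origin.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(kind = c("grid", "random_planar", "path", "star"),
                         rows = 3, cols = 3, node_count = 50,
                         edge_length_m = 500,
                         speed_set = c(30, 50, 60, 80),
                         missing_speed_frac = 0,
                         congestion = NULL,
                         k_max = 100,
                         facility_count = 2,
                         demand_count = 10,
                         seed = 1L,
                         allow_disconnected = FALSE,
                         origin = c(46.7, 24.7)) {
  kind <- match.arg(kind)
  stopifnot(edge_length_m > 0, k_max > 0, facility_count >= 1,
            demand_count >= 0, missing_speed_frac >= 0,
            missing_speed_frac <= 1)
  if (!is.null(congestion)) {
    stopifnot(length(congestion) %in% 1:2, all(congestion >= 0),
              all(congestion <= 1))
  }
  structure(as.list(environment()), class = "fixture_spec")
}

grid_skeleton <- function(spec) {
  rows <- spec$rows; cols <- spec$cols; s <- spec$edge_length_m
  idx <- function(r, c) (r - 1L) * cols + c
  ids <- sprintf("n%03d", seq_len(rows * cols))
  rc <- expand.grid(c = seq_len(cols), r = seq_len(rows))
  xy <- offset_lonlat(spec$origin[1], spec$origin[2],
                      (rc$c - 1) * s, (rc$r - 1) * s)
  nodes <- data.frame(node_id = ids, lon = xy[, "lon"], lat = xy[, "lat"],
                      stringsAsFactors = FALSE)
  eu <- c(); ev <- c()
  for (r in seq_len(rows)) for (c in seq_len(cols)) {
    if (c < cols) { eu <- c(eu, idx(r, c)); ev <- c(ev, idx(r, c + 1L)) }
    if (r < rows) { eu <- c(eu, idx(r, c)); ev <- c(ev, idx(r + 1L, c)) }
  }
  list(nodes = nodes,
       edges = data.frame(u = ids[eu], v = ids[ev],
                          length_m = spec$edge_length_m,
                          stringsAsFactors = FALSE))
}

path_skeleton <- function(spec) {
  n <- spec$node_count
  ids <- sprintf("n%03d", seq_len(n))
  xy <- offset_lonlat(spec$origin[1], spec$origin[2],
                      (seq_len(n) - 1) * spec$edge_length_m, 0)
  list(nodes = data.frame(node_id = ids, lon = xy[, "lon"], lat = xy[, "lat"],
                          stringsAsFactors = FALSE),
       edges = data.frame(u = ids[-n], v = ids[-1],
                          length_m = spec$edge_length_m,
                          stringsAsFactors = FALSE))
}

star_skeleton <- function(spec) {
  n <- spec$node_count
  stopifnot(n >= 2)
  ids <- sprintf("n%03d", seq_len(n))
  ang <- 2 * pi * (seq_len(n - 1) - 1) / (n - 1)
  xy <- offset_lonlat(spec$origin[1], spec$origin[2],
                      c(0, spec$edge_length_m * cos(ang)),
                      c(0, spec$edge_length_m * sin(ang)))
  list(nodes = data.frame(node_id = ids, lon = xy[, "lon"], lat = xy[, "lat"],
                          stringsAsFactors = FALSE),
       edges = data.frame(u = ids[1], v = ids[-1],
                          length_m = spec$edge_length_m,
                          stringsAsFactors = FALSE))
}

random_planar_skeleton <- function(spec) {
  n <- spec$node_count
  side <- sqrt(n) * 400  # ~street-block density, meters
  ids <- sprintf("n%03d", seq_len(n))
  xs <- runif(n, 0, side)
  ys <- runif(n, 0, side)
  xy <- offset_lonlat(spec$origin[1], spec$origin[2], xs, ys)
  nodes <- data.frame(node_id = ids, lon = xy[, "lon"], lat = xy[, "lat"],
                      stringsAsFactors = FALSE)
  # proximity connection: join each node to its 3 nearest neighbors
  d2 <- as.matrix(stats::dist(cbind(xs, ys)))
  diag(d2) <- Inf
  pairs <- matrix(integer(0), ncol = 2)
  for (i in seq_len(n)) {
    nn <- order(d2[i, ])[seq_len(min(3L, n - 1L))]
    pairs <- rbind(pairs, cbind(pmin(i, nn), pmax(i, nn)))
  }
  pairs <- unique(pairs)
  # connectivity repair: bridge closest inter-component node pairs
  if (!spec$allow_disconnected) {
    repeat {
      g <- igraph::graph_from_edgelist(pairs, directed = FALSE)
      g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
      memb <- igraph::components(g)$membership
      if (max(memb) == 1L) break
      in1 <- which(memb == 1L)
      out1 <- which(memb != 1L)
      sub <- d2[in1, out1, drop = FALSE]
      k <- arrayInd(which.min(sub), dim(sub))
      pairs <- rbind(pairs, c(min(in1[k[1]], out1[k[2]]),
                              max(in1[k[1]], out1[k[2]])))
    }
  }
  len <- geosphere::distHaversine(
    cbind(nodes$lon[pairs[, 1]], nodes$lat[pairs[, 1]]),
    cbind(nodes$lon[pairs[, 2]], nodes$lat[pairs[, 2]]))
  list(nodes = nodes,
       edges = data.frame(u = ids[pairs[, 1]], v = ids[pairs[, 2]],
                          length_m = len, stringsAsFactors = FALSE))
}

#' Generate a synthetic fixture
#'
#' Builds the road network, facility set and demand sample described by a
#' [fixture_spec()]. The same spec and seed always produce identical output;
#' the caller's RNG state is left untouched.
#'
#' @param spec A [fixture_spec()].
#' @param config An [app_config()] supplying defaults for edges generated
#'   without a speed limit.
#' @return List with elements `network` ([road_network()]), `facilities`
#'   (snapped [facility_set()]), `demands` (data frame `lon`, `lat`) and
#'   `spec`.
#' @export
make_fixture <- function(spec, config = app_config()) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    skel <- switch(spec$kind,
                   grid = grid_skeleton(spec),
                   random_planar = random_planar_skeleton(spec),
                   path = path_skeleton(spec),
                   star = star_skeleton(spec))
    n_nodes <- nrow(skel$nodes)
    if (spec$facility_count > n_nodes) {
      stop("facility_count exceeds node count", call. = FALSE)
    }
    e <- skel$edges
    m <- nrow(e)
    e$edge_id <- sprintf("e%04d", seq_len(m))
    speed <- if (length(spec$speed_set) == 1L) {
      rep(spec$speed_set, m)
    } else {
      sample(spec$speed_set, m, replace = TRUE)
    }
    if (spec$missing_speed_frac > 0) {
      gap <- sample(m, round(spec$missing_speed_frac * m))
      speed[gap] <- NA_real_
    }
    e$speed_limit_kmh <- speed
    e$k_max <- spec$k_max
    sat <- if (is.null(spec$congestion)) {
      rep(0, m)
    } else if (length(spec$congestion) == 1L) {
      rep(spec$congestion, m)
    } else {
      runif(m, spec$congestion[1], spec$congestion[2])
    }
    # vehicle counts chosen so density / k_max reproduces the drawn ratio
    e$vehicle_count <- sat * spec$k_max * e$length_m / 1000
    net <- road_network(skel$nodes, e, config)

    fac_nodes <- sample(net$nodes$node_id, spec$facility_count)
    fs <- facility_set(data.frame(
      facility_id = sprintf("p%02d", seq_len(spec$facility_count)),
      name = sprintf("station %02d", seq_len(spec$facility_count)),
      lon = net$nodes$lon[match(fac_nodes, net$nodes$node_id)],
      lat = net$nodes$lat[match(fac_nodes, net$nodes$node_id)],
      available = 1L,
      stringsAsFactors = FALSE))
    fs <- suppressWarnings(snap_facilities(net, fs))

    dm <- if (spec$demand_count > 0) {
      dn <- sample(net$nodes$node_id, spec$demand_count, replace = TRUE)
      base <- net$nodes[match(dn, net$nodes$node_id), ]
      jit <- offset_lonlat(base$lon, base$lat,
                           runif(spec$demand_count, -10, 10),
                           runif(spec$demand_count, -10, 10))
      data.frame(lon = jit[, "lon"], lat = jit[, "lat"])
    } else {
      data.frame(lon = numeric(0), lat = numeric(0))
    }
    list(network = net, facilities = fs, demands = dm, spec = spec)
  })
}

#' City-scale synthetic scenario
#'
#' A ready-made scenario mirroring the conditions of a metropolitan EMS
#' deployment: a random planar road network of about 500 nodes, 30 ambulance
#' stations, mixed speed limits with roughly 30% of segments carrying no
#' posted limit (those fall back to the 40 km/h default), and a uniform
#' saturation level of 0.70 on every segment.
#'
#' @param seed Integer seed.
#' @param node_count Network size; 500 by default.
#' @return As [make_fixture()].
#' @export
riyadh_like <- function(seed = 1L, node_count = 500) {
  make_fixture(fixture_spec(
    kind = "random_planar",
    node_count = node_count,
    speed_set = c(30, 50, 60, 80),
    missing_speed_frac = 0.3,
    congestion = 0.70,
    facility_count = 30,
    demand_count = 50,
    seed = seed))
}

#' Write a fixture to an output directory
#'
#' Emits `network.csv` + `nodes.csv` (edge-list dialect), `network.geojson`,
#' `facilities.csv` and `demands.csv`, all re-readable by the road_network
#' readers.
#'
#' @param fix A [make_fixture()] result.
#' @param out_dir Directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_fixture <- function(fix, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_network(fix$network, file.path(out_dir, "network.csv"),
                format = "edge_csv",
                nodes_path = file.path(out_dir, "nodes.csv"))
  write_network(fix$network, file.path(out_dir, "network.geojson"),
                format = "geojson_lines")
  write_facilities(fix$facilities, file.path(out_dir, "facilities.csv"))
  write.csv(data.frame(lon = fix$demands$lon, lat = fix$demands$lat),
            file.path(out_dir, "demands.csv"), row.names = FALSE,
            quote = FALSE)
  invisible(out_dir)
}
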