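#' Free-flow traversal time of a road segment
#'
#' Time to traverse a segment of `length_m` meters at its allowed speed with
#' no congestion: `(length_m / (1000 * speed_kmh)) * 3600` seconds.
#'
#' @param length_m Segment length in meters, > 0.
#' @param speed_kmh Allowed speed in km/h, > 0.
#' @return Seconds.
#' @examples
#' free_flow_time(1000, 36) # 100 s
#' @export
free_flow_time <- function(length_m, speed_kmh) {
  if (any(!is.finite(length_m) | length_m <= 0)) {
    stop("length_m must be > 0", call. = FALSE)
  }
  if (any(!is.finite(speed_kmh) | speed_kmh <= 0)) {
    stop("speed_kmh must be > 0", call. = FALSE)
  }
  (length_m / (1000 * speed_kmh)) * 3600
}

#' Traffic density of a road segment
#'
#' Vehicles per kilometer: `vehicle_count * 1000 / length_m`.
#'
#' @param vehicle_count Number of vehicles occupying the segment, >= 0.
#' @param length_m Segment length in meters, > 0.
#' @return Vehicles per km.
#' @examples
#' traffic_density(30, 1000) # 30 veh/km
#' @export
traffic_density <- function(vehicle_count, length_m) {
  if (any(!is.finite(length_m) | length_m <= 0)) {
    stop("length_m must be > 0", call. = FALSE)
  }
  if (any(vehicle_count < 0)) {
    stop("vehicle_count must be >= 0", call. = FALSE)
  }
  vehicle_count * 1000 / length_m
}

#' Saturation ratio of a road segment
#'
#' The current traffic density over the segment's maximum (jam) density,
#' `k / k_max`; 0 means an empty road, 1 a jammed one. The ratio is clamped
#' at `clamp_max` (default 0.95) so that the congested travel time of the
#' division formula stays finite: traffic flow near jam density is erratic
#' and outside the model's intended operating range.
#'
#' @param density Current density, veh/km, >= 0.
#' @param k_max Maximum density, veh/km, > 0.
#' @param clamp_max Upper clamp, in (0, 1).
#' @return Dimensionless ratio in `[0, clamp_max]`.
#' @examples
#' saturation_ratio(70, 100) # 0.70
#' @export
saturation_ratio <- function(density, k_max, clamp_max = 0.95) {
  if (any(!is.finite(k_max) | k_max <= 0)) {
    stop("k_max must be > 0", call. = FALSE)
  }
  if (any(density < 0)) stop("density must be >= 0", call. = FALSE)
  pmin(density / k_max, clamp_max)
}

#' Congestion-adjusted travel time of one segment
#'
#' Combines length, speed limit and saturation flow into the edge weight
#' used by time-based routing. Two functional forms are provided via
#' `mode`:
#'
#' * `"greenshields_division"` (default): `t = t_free / (1 - k/k_max)` —
#'   travel time grows without bound as density approaches jam density,
#'   matching the physical expectation that congestion slows traffic.
#' * `"as_printed"`: `t = t_free * (1 - k/k_max)` — the literal
#'   multiplicative form, kept selectable for fidelity even though it makes
#'   congested segments *faster*; see the methods vignette for why the
#'   division form is the default.
#'
#' Both forms use the clamped saturation ratio and reduce exactly to the
#' free-flow time on an empty segment.
#'
#' @param segment A one-row data frame (or list) with `edge_id`, `length_m`,
#'   `speed_limit_kmh`, `vehicle_count`, `k_max` — e.g. a row of
#'   `net$edges`.
#' @param mode Formula mode, see above.
#' @param clamp_max Saturation clamp, see [saturation_ratio()].
#' @return A one-row data frame with columns `edge_id`, `t_free_s`,
#'   `density_veh_per_km`, `saturation_ratio`, `t_travel_s`, `formula_mode`.
#' @examples
#' seg <- data.frame(edge_id = "e1", length_m = 1000, speed_limit_kmh = 36,
#'                   vehicle_count = 70, k_max = 100)
#' travel_time(seg)$t_travel_s                      # 100 / 0.3
#' travel_time(seg, mode = "as_printed")$t_travel_s # 100 * 0.3
#' @export
travel_time <- function(segment,
                        mode = c("greenshields_division", "as_printed"),
                        clamp_max = 0.95) {
  mode <- match.arg(mode)
  t_free <- free_flow_time(segment$length_m, segment$speed_limit_kmh)
  dens <- traffic_density(segment$vehicle_count, segment$length_m)
  sat <- saturation_ratio(dens, segment$k_max, clamp_max)
  t_trav <- if (mode == "greenshields_division") {
    t_free / (1 - sat)
  } else {
    t_free * (1 - sat)
  }
  data.frame(edge_id = as.character(segment$edge_id),
             t_free_s = t_free,
             density_veh_per_km = dens,
             saturation_ratio = sat,
             t_travel_s = t_trav,
             formula_mode = mode,
             stringsAsFactors = FALSE)
}

#' Travel-time weights for every edge of a network
#'
#' Vectorized [travel_time()] over all edges. If `saturation_override` is
#' given (e.g. the scenario preset 0.70), it replaces the per-edge
#' density-derived ratio on every edge, emulating a network-wide congestion
#' level when no vehicle counts are observed.
#'
#' @param net A [road_network()].
#' @inheritParams travel_time
#' @param saturation_override Optional constant saturation ratio applied to
#'   all edges (clamped at `clamp_max`).
#' @return A data frame with one row per edge, columns as in
#'   [travel_time()]; row order follows `net$edges`.
#' @export
weight_all_edges <- function(net,
                             mode = c("greenshields_division", "as_printed"),
                             clamp_max = 0.95,
                             saturation_override = NULL) {
  stopifnot(inherits(net, "road_network"))
  mode <- match.arg(mode)
  e <- net$edges
  t_free <- free_flow_time(e$length_m, e$speed_limit_kmh)
  dens <- traffic_density(e$vehicle_count, e$length_m)
  sat <- saturation_ratio(dens, e$k_max, clamp_max)
  if (!is.null(saturation_override)) {
    if (saturation_override < 0) {
      stop("saturation_override must be >= 0", call. = FALSE)
    }
    sat <- rep(min(saturation_override, clamp_max), nrow(e))
  }
  t_trav <- if (mode == "greenshields_division") t_free / (1 - sat) else t_free * (1 - sat)
  data.frame(edge_id = e$edge_id,
             t_free_s = t_free,
             density_veh_per_km = dens,
             saturation_ratio = sat,
             t_travel_s = t_trav,
             formula_mode = mode,
             stringsAsFactors = FALSE)
}

#' Named per-edge cost vectors for routing
#'
#' Convenience extractors turning a network (plus weight options) into the
#' named cost vector consumed by [build_nvd()], [rank_candidates()] and
#' [as_igraph()].
#'
#' @inheritParams weight_all_edges
#' @return A named numeric vector, names are `edge_id`s.
#' @export
time_weights <- function(net,
                         mode = c("greenshields_division", "as_printed"),
                         clamp_max = 0.95, saturation_override = NULL) {
  ew <- weight_all_edges(net, mode, clamp_max, saturation_override)
  setNames(ew$t_travel_s, ew$edge_id)
}

#' @rdname time_weights
#' @export
distance_weights <- function(net) {
  stopifnot(inherits(net, "road_network"))
  setNames(net$edges$length_m, net$edges$edge_id)
}
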