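# catchroute

Network Voronoi catchments and time-based Dijkstra routing for emergency
medical services (EMS).

When an ambulance is dispatched, "nearest station" measured in straight-line
or even road distance can be the wrong answer: under congestion the
shortest road is often not the fastest one. `catchroute` implements a
spatial accessibility and dispatch model for EMS planners and health
geographers that

1. models the road network as a weighted undirected graph *G = (N, L)*,
2. weights each road segment by its **congestion-adjusted travel time**
   rather than its length,
3. partitions the network into **station catchment areas** — a network
   Voronoi diagram (NVD) in which every node belongs to the station that is
   cheapest to reach along the network, and
4. selects the dispatch unit through a **four-phase procedure**: locate the
   demand's catchment, assemble candidates (home station plus stations in
   adjacent catchments, respecting unit availability, expanding ring by
   ring over the catchment adjacency graph when necessary), rank candidates
   by time-based shortest path, and select the minimum.

## The travel-time model

For a segment *l* of length *d* (m) with speed limit *s* (km/h), the
free-flow traversal time is

    t_free = d / (1000 s) × 3600   [seconds]

With *n* vehicles on the segment, the traffic density is *k = 1000 n / d*
(veh/km), and the saturation ratio is *k / k_max*, where *k_max* is the
segment's jam density. The default travel-time form is

    t = t_free / (1 − k/k_max)

so an empty road costs its free-flow time and travel time grows without
bound as the segment approaches jam density (the ratio is clamped at 0.95
to keep it finite). A literal multiplicative form
`t = t_free × (1 − k/k_max)` is also available as `formula_mode =
"as_printed"`; see the methods vignette for why it is not the default.
Catchments are built with a single **multi-source Dijkstra** sweep seeded
at all station nodes; cost ties go to the lexicographically smallest
station id, making every result deterministic.

## Worked example

```r
library(catchroute)

fix <- riyadh_like(seed = 42, node_count = 300)   # synthetic city scenario
net <- fix$network; fs <- fix$facilities

w   <- time_weights(net)            # congestion-adjusted seconds per edge
ca  <- build_nvd(net, fs, w)        # network Voronoi catchments
adj <- adjacency(net, ca)           # catchment adjacency graph

ca
#> <catchment_assignment> 300 nodes over 30 facilities (time_s); 0 unreachable
adj
#> <catchment_adjacency> 30 catchments, 84 boundary edges, mean degree 2.9

res <- dispatch(net, fs, ca, adj, w,
                dispatch_request(lon = fix$demands$lon[1],
                                 lat = fix$demands$lat[1]))
res
#> <dispatch_result> demand n102 (home p14) -> p14 (121.9 s, home_catchment; 6 candidates)

route_costs(net, res$selected$path[[1]])[c("distance_m", "time_s_free", "time_s_division")]
#> $distance_m: 508.3   $time_s_free: 36.6   $time_s_division: 121.9
```

The demand snaps to node `n102`, whose catchment belongs to station `p14`;
with all units available the home station is (provably) the fastest, at
121.9 s of congested travel time over a 508 m route that would take 36.6 s
on an empty road — the factor 1/(1 − 0.70) ≈ 3.33 of the scenario's
uniform saturation level 0.70. Marking `p14` out of service falls back to
the adjacent catchments:

```r
dispatch(net, fs, ca, adj, w,
         dispatch_request(lon = fix$demands$lon[1], lat = fix$demands$lat[1],
                          availability_override = c(p14 = 0)))
#> <dispatch_result> demand n102 (home p14) -> p30 (227.3 s, adjacent_catchment; 5 candidates)
```

## Command line

The same pipeline is scriptable via `exec/catchroute` (or
`catchroute::run_cli()`):

```sh
catchroute make-fixture --kind riyadh_like --seed 7 --out-dir demo
catchroute build-catchments --network demo/network.csv --nodes demo/nodes.csv \
    --facilities demo/facilities.csv --weight time --out demo/catchments.geojson
catchroute dispatch --network demo/network.csv --nodes demo/nodes.csv \
    --facilities demo/facilities.csv --demand "46.71,24.72" --out demo/result.json
catchroute route ... --facility p05 --out demo/route.geojson
```

Networks are read from an edge-list CSV
(`edge_id,u,v,length_m,speed_kmh,vehicle_count,k_max`, plus an optional
`node_id,lon,lat` companion file) or from a GeoJSON LineString collection;
catchments and routes are written as GeoJSON, dispatch results as JSON with
a per-phase audit log.

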