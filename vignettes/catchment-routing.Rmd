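---
title: "Catchment areas and time-based dispatch: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Catchment areas and time-based dispatch: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catchroute)
```

## The problem

Emergency medical dispatch must answer two questions quickly: *which
station serves this location?* and *which available unit reaches it
fastest?* Both are spatial-network questions. `catchroute` answers them
with a network Voronoi diagram (NVD) over the road graph — each station's
catchment is the set of nodes it can reach more cheaply than any other
station — and a four-phase selection that respects unit availability. The
key modeling commitment is that "cheap" is measured in *travel time under
congestion*, not in meters: in dense traffic the two orderings differ, and
for time-critical service the time ordering is the right one.

## Road network model

The network is a weighted **undirected** graph. Nodes carry WGS84
coordinates; edges are road segments with a length `length_m`, a speed
limit `speed_limit_kmh`, a current `vehicle_count` and a jam density
`k_max`. One-way streets, turn restrictions and elevation are out of
scope. Stations and incidents are anchored to *nodes* (nearest node by
great-circle distance); the selection logic is defined entirely over
nodes, so edges are never split at equidistant interior points — catchments
are node sets and the diagram's boundary is reported as the set of edges
whose endpoints carry different labels. Geometry is used only for
snapping; all routing follows `length_m` along edges.

## Travel-time edge weights

For a segment of length $d$ meters and speed limit $s$ km/h:

$$t_{\mathrm{free}} = \frac{d}{1000\,s} \times 3600 \quad [\mathrm{s}],
\qquad k = \frac{1000\,n}{d} \quad [\mathrm{veh/km}],
\qquad \rho = \min\!\left(\frac{k}{k_{\max}},\, 0.95\right).$$

Two functional forms tie the saturation ratio $\rho$ to travel time:

* **`greenshields_division`** (default): $t = t_{\mathrm{free}} / (1 - \rho)$.
* **`as_printed`**: $t = t_{\mathrm{free}} \times (1 - \rho)$.

The multiplicative form is the literal transcription of the source
formula, but it makes congested segments *cheaper*, which contradicts both
physical intuition and the reported direction of effect (time-based route
costs exceeding length-based ones). We therefore default to the division
form, which is the travel-time expression obtained from the classical
Greenshields speed–density relation in its low-density linearization: at
$\rho = 0$ both forms equal $t_{\mathrm{free}}$ exactly, and the division
form increases monotonically in density. The printed form remains
selectable so that either reading can be reproduced; nothing in the
package silently "corrects" one into the other.

The clamp at $\rho \le 0.95$ keeps the division finite. Flow near jam
density is empirically erratic and the model is not meant to be evaluated
there; the clamp value is a config knob (`saturation_clamp`). Travel time
is treated as running time only — the saturation term *is* the delay
model; no separate intersection or signal delay is added.

### Defaults and their units

| parameter | default | unit | role |
|---|---|---|---|
| `default_speed_kmh` | 40 | km/h | speed for segments with no posted limit |
| `default_k_max` | 100 | veh/km | jam density where none is supplied |
| `saturation_clamp` | 0.95 | — | upper bound on $\rho$ |
| `default_saturation` | 0.70 | — | network-wide scenario preset |
| `formula_mode` | `greenshields_division` | — | congestion form |

A missing `vehicle_count` defaults to 0, so absent any traffic data the
time weight reduces to the free-flow time and time-based routing reduces
to speed-scaled distance routing.

## Catchment construction

`build_nvd()` runs **one multi-source Dijkstra sweep** seeded at every
station anchor with cost 0. This is implemented in the package itself (a
CSR adjacency structure and an $O(n^2 + m)$ settle loop — graphs here are
city-scale, a few thousand nodes at most) rather than as per-station
single-source runs, which instead serve as the *independent oracle* in the
test suite: on every test network the sweep's labels and costs must equal
the per-station argmin computed by `igraph` exactly.

Numerical choices, stated explicitly:

* **Tie rule.** A node equidistant from several stations is labeled with
  the lexicographically smallest `facility_id` (C-locale byte order, so
  results do not depend on the session locale). Ties are resolved in a
  second pass over the shortest-path DAG — edges with
  $\mathrm{dist}[u] + w = \mathrm{dist}[v]$, processed in increasing
  distance order — which provably reproduces the per-station
  argmin-with-ties rule rather than an arbitrary settle order.
* **Float equality.** The DAG pass uses exact floating-point equality.
  Each node's actual Dijkstra parent satisfies the equality by
  construction, so unique minima are always labeled correctly; alternative
  equal-cost routes are recognized when their sums are bitwise equal,
  which holds for the integer-valued weights used in designed tie
  fixtures. On continuous random weights, exact ties have probability
  zero.
* **Degenerate inputs.** Stations sharing an anchor are allowed (warned);
  the dominated one gets an empty catchment. Nodes in components with no
  station are reported `unreachable`, and locating a demand there raises a
  no-coverage error instead of a silent worst case.
* **Availability.** By default *all* stations generate catchments and
  availability is handled at dispatch time; `active_only = TRUE` excludes
  out-of-service stations from the diagram itself.

Two catchments are *adjacent* when a road edge joins them;
`adjacency()` returns this graph plus the boundary edges. It is the
fallback search space for dispatch.

## The four-phase dispatch

1. **Locate** — snap the incident, read its catchment label (its *home*
   station).
2. **Candidates** — if the home station has a unit, candidates are the
   home plus the available stations in adjacent catchments; if not, the
   available adjacent stations; if none, expand breadth-first over the
   catchment adjacency graph (neighbors of neighbors, ring by ring) and
   stop at the first ring containing any available station. One design
   choice deserves emphasis: *availability filters every branch*. The
   home-available case could be read as admitting all adjacent stations
   regardless of availability, but dispatching a station with no unit is
   meaningless, so unavailable stations are never candidates.
3. **Rank** — one Dijkstra rooted at the demand node under the time
   weights (the graph is undirected, so demand→station equals
   station→demand), sorted by `(travel_time_s, facility_id)`. Each
   candidate's reported time is the sum of its route's edge weights.
4. **Select** — the head of the ranking; the full ranking, route and a
   per-phase audit log are returned.

Two provable properties anchor the test suite. *Home-optimality*: when the
ranking weights equal the NVD weights and all units are available, the
selected station is always the demand's own label — the candidate set
contains the home station, and no station anywhere beats it by
construction of the NVD. *First-ring monotonicity*: while candidates stay
within the home and its adjacent ring, removing units can only raise the
selected travel time (the candidate set shrinks, and any shortest path to
a non-adjacent station must cross an adjacent catchment, so it costs at
least as much as that catchment's station). The second guarantee *stops at
ring expansion*: once home and every neighbor are down, a second-ring
station may legitimately be time-closer than a first-ring station that was
removed earlier, so selected time may drop. The property test exercises
exactly the regime where the guarantee holds; the expansion regime is
instead verified as "exact argmin over the constructed candidate set",
which is what the algorithm promises there.

## Synthetic scenario generator

All testing runs on seeded synthetic fixtures (`make_fixture()`): grids,
paths, stars, and random planar networks built by uniform point scatter,
3-nearest-neighbor joining and connectivity repair — a cheap proxy for the
low-degree, locally-connected structure of street networks.
Per-edge vehicle counts are derived from a requested saturation ratio so
the congestion level is controlled exactly. The city-scale preset
(`riyadh_like()`) encodes the deployment conditions the model targets: a
~500-node network, **30 ambulance stations**, mixed speed limits with
~30% of segments carrying no posted limit (exercising the **40 km/h**
default), and a uniform saturation of **0.70** — below that level capacity
is generally considered sufficient, while towards 1 flow breaks down.

What the generator does *not* emulate: real street geometry and turn
logic, heterogeneous per-segment jam densities, time-varying traffic, and
empirically calibrated volumes. Passing tests therefore demonstrate the
correctness of the catchment and dispatch machinery under controlled
conditions, not predictive accuracy of travel times on a real city.

Problem sizes used by the suite, chosen to make the oracle comparisons
exhaustive while staying desk-scale: oracle equivalence on 50 random
networks of 40–300 nodes and 2–10 stations; home-optimality on 50
fixtures × 200 demand nodes; ranking checked against exhaustive simple-path
enumeration on small grids; the end-to-end scenario at 300–500 nodes. The
full suite runs in under a minute on one core.

## Known limitations

* Undirected edges only; dual carriageways and one-way systems collapse to
  a single bidirectional segment.
* Catchments are node sets; no polygonal (cartographic) rendering beyond
  optional convex hulls, which can overlap for interleaved catchments.
* Saturation is a per-edge constant at query time; there is no temporal
  traffic profile or stochastic travel-time model.
* Single-incident, single-unit dispatch: no queueing of simultaneous
  calls, no relocation policies, no routing onward to hospital.
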