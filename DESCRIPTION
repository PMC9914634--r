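Package: catchroute
Title: Network Voronoi Catchments and Time-Based Dijkstra Routing for
    Emergency Medical Services
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Delineates service catchment areas for emergency medical
    service (EMS) stations as network Voronoi diagrams over a road graph,
    weights road segments by congestion-adjusted travel time derived from
    traffic density and saturation flow, and selects the dispatch unit with
    the minimum travel time through a four-phase procedure with
    adjacent-catchment fallback when the home unit is unavailable. Includes
    readers and writers for edge-list CSV and GeoJSON road networks, a
    seeded synthetic road-network generator for grids, paths, stars and
    random planar graphs, and a command-line interface covering fixture
    generation, catchment construction, dispatch and route export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
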