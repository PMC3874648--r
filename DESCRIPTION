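Package: pedshed
Title: Agent-Based Walkable Catchment and Pedshed Analysis on Street Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates simple pedestrian agents traversing a street or sidewalk
    network from an origin of interest under walking-speed, time-or-distance and
    intersection-wait constraints. Builds a noded network graph from line features
    (GeoJSON), snaps origins and destinations onto it, computes time-budgeted
    reachability (earliest arrivals, reached edges and frontier fragments),
    exports equally spaced time-stamped agent traces, and derives walkability
    metrics: the buffered network catchment, the pedshed ratio against the
    equivalent circular buffer, and the mean number of intersections crossed.
    Includes what-if scenario editing (adding or removing street segments,
    toggling signals, barriers with limited crossings) and synthetic network
    generators (grids, cul-de-sac suburbs, river barriers) for fully
    self-contained experiments. A command-line interface wraps the full
    run/edit/compare workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    grDevices,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
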