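---
title: "Walkable catchments with simple agents: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Walkable catchments with simple agents: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedshed)
```

## The problem

Walkability analysis asks how much of a neighborhood is genuinely within
walking reach of an origin of interest — a school, a railway station, a
clinic. The naive answer, a circle of radius `speed × time`, ignores street
connectivity, signals, slopes and barriers, and overestimates access; the
ratio between the true network catchment and that circle (the *pedshed
ratio*) is therefore a standard summary of network permeability. `pedshed`
computes it with a simple agent model: simulated pedestrians with fixed
rules (no learning, no interaction), released from the origin in all
directions.

## The model, step by step

**Network.** Input line features are *noded*: split at every mutual
crossing and endpoint contact, with coincident endpoints within a tolerance
merged into intersection nodes. Edges keep polyline geometry; degree-2
vertices interior to a line are geometry, not intersections. The graph is
undirected — pedestrians walk both ways on any segment; one-way streets are
out of scope. Edges carry an optional percent gradient and a `passable`
flag (barriers such as rivers are impassable edges), nodes an optional
signal flag and wait override.

**Cost of walking.** Under a *time* budget, a path costs the sum of edge
traversal times at the gradient-adjusted speed
`v_e = v · max(0.2, 1 − p · g_e)` plus the intersection wait at every node
interior to the path. Under a *distance* budget the cost is length alone.
Exactly one of the two budgets is set: each mode has one budget currency,
so waits — which consume time, not meters — do not affect distance-budgeted
reach (they still appear in trace timestamps, which are always seconds).

**Waits.** The wait is charged when an agent passes *through* an eligible
node: a pedestrian does not wait at a light they never cross, so the origin
and the final stop are wait-free. Eligibility defaults to signalized nodes
only (`wait_scope = "signalized_only"`, matching a traffic-signals data
layer); `"all_intersections"` extends it to every degree ≥ 3 node for
networks without signal data. A per-node `wait_override` takes precedence.
An agent whose remaining budget is eaten mid-wait stops *at* that node and
is not counted as having crossed it.

**Reachability.** Earliest arrivals are single-source shortest generalized
costs, computed once by shortest-path expansion (igraph's Dijkstra over a
directed arc view with the head-node wait folded into each arc, then
subtracted — which is what makes terminal nodes wait-free) rather than by
literally stepping thousands of agents; results are identical and the cost
is a single graph traversal. Arrival at a node is *before* any wait there.
An edge is **reached** when every point of it is within budget (the union
of directional coverage spans the edge); where the budget dies mid-edge the
covered part is a **frontier fragment**, cut exactly where the residual
budget reaches zero at the edge's effective speed. Snapped origins insert a
temporary vertex that splits the host edge for the computation and never
mutates user data.

**Agents.** Destinations are sampled uniformly by network length over
*passable* edges (an impassable edge is a barrier, not a place to walk to),
reproducibly from the seed. Each agent follows the cost-optimal path found
by A-Star under the straight-line heuristic (Euclidean distance, divided by
the flat-ground speed in time mode). The heuristic is admissible and
consistent: waits are nonnegative and gradients only slow agents, so the
straight line never overestimates — A-Star provably returns Dijkstra
costs, and the tests check this identity on hundreds of random
origin–destination pairs. Paths become traces: points every
`trace_spacing` meters along the walk, timestamps accumulating travel plus
waits (so the timestamp jumps by the wait across a signalized node), agents
stopping at the frontier with `completed = FALSE` when the destination is
out of budget.

**Metrics.** The catchment is the reached geometry buffered by
`buffer_width` per side with round caps — the standard pedshed
operationalization. The comparison circle uses the *gross* radius
`r = v · max_time` (or the distance budget): the circle represents the
naive no-network, no-wait estimate being critiqued, so waits depress the
ratio, not the denominator. Intersections crossed are interior path nodes
of degree ≥ 3; percent deltas in scenario comparisons use the "before"
scenario as denominator and are undefined (NA) on a zero baseline.

## Parameters

| Parameter | Units | Default | Range | Notes |
|---|---|---|---|---|
| `walking_speed` | m/s | 1.4 | (0, 2] | typical adult pace; cap mirrors the tool's slider |
| `max_time` | s | — | (0, 1200] | XOR with `max_distance` |
| `max_distance` | m | — | > 0 | XOR with `max_time` |
| `intersection_wait` | s | 0 | [0, 60] | per eligible crossing |
| `wait_scope` | — | signalized_only | | see above |
| `gradient_penalty` | /% slope | 0 | [0, 0.1] | off by default so the feature never surprises; speed floored at 0.2·v |
| `n_destinations` | — | 500 | ≥ 1 | one agent each |
| `trace_spacing` | m | 5 | > 0 | trace point spacing |
| `buffer_width` | m | 50 | > 0 | catchment half-width |
| `noding_tolerance` | m | 0.1 | | typical centerline digitizing precision |

The hard caps (2 m/s, 20 min, 60 s) are enforced at configuration time and
at the command line; `enforce_limits = FALSE` (CLI `--no-limits`) lifts
them for research use, loudly.

## Numerical choices

- **Catchment area and polygon.** The buffered union is extracted by
  marching squares (`grDevices::contourLines`) on the *exact* Euclidean
  distance field of the covered segments, contoured at `buffer_width`. The
  reported area is the shoelace area of the resulting rings (holes
  negative), so exported polygons agree with reported areas to machine
  precision. The grid is anchored to the *network* bounding box, making
  areas comparable — and provably monotone — across parameter sweeps on the
  same network; its anchor is offset by an irrational fraction of the cell
  so axis-aligned networks never place field values exactly on the contour
  level (a degenerate case for marching squares). Where the field is linear
  (straight edges) the interpolated contour is exact at any resolution;
  curvature error on caps is O(h²/w). The default resolution `w/10`
  (capped at `w/3`) keeps the single-road closed-form case within ~10⁻³
  relative; tests that need tighter agreement pass `resolution` explicitly.
- **Tie-breaking** is deterministic everywhere: lowest edge id then lowest
  offset for snapping ties, first-index `which.min` in A-Star, seeded
  sampling elsewhere — identical seed, config and network give bit-identical
  outputs, and the acceptance tests compare file checksums.
- **Degenerate inputs.** Zero-length noding leftovers are collapsed into
  their node (they break traversal cost math); the validator flags, and
  never drops, zero-length edges it is given. Empty reachability yields an
  empty polygon of area 0. Collinear overlapping input lines are split at
  each other's endpoints but not deduplicated — topology repair of badly
  digitized data is out of scope.
- **CRS policy.** Degree-like coordinates are rejected, not silently
  reprojected: every speed and length in the model is metric. Declaring
  `crs_units = "m"` overrides the heuristic for small metric extents.

## What the synthetic networks do and do not show

The generators produce orthogonal grids (with a seeded fraction of
signalized intersections), a single road, a cul-de-sac comb with a proposed
tip-to-tip connector, and river barriers with a chosen number of crossings.
They are geometry-first — real coordinates flowing through the same noding,
snapping and buffering code as imported data — and they pin down analytic
ground truth: `r = v·t` reach on the road, the capsule area
`2wL + πw²`, exact wait arithmetic on a signalized corridor, and the
dense-grid pedshed limit 2/π. What they do *not* emulate: irregular block
sizes and curved streets, dead-end alleys mixed with arterials, gradient
fields, or sidewalk-vs-centerline offsets. Passing tests therefore
demonstrate correctness of the machinery, not calibration to any real
city's walking behavior; with real data the model remains a simple-agent
idealization (no congestion, no route preference beyond cost).

Problem sizes in the test-suite and acceptance runs are desk-scale by
design — grids up to 41×41 (1681 nodes, 3280 edges), 100 random networks
against a Bellman-Ford oracle, 500 A-Star/Dijkstra pairs, 200-agent runs —
sizes at which every check completes in seconds while still exercising
multi-component, barrier and frontier cases.

## Known limitations

- GeoJSON only; no shapefile codec (convert externally).
- Undirected network: no one-way or turn restrictions.
- No agent–agent interaction or congestion; building avoidance is implicit
  in network constraint. These are "complex agent" extensions.
- The pedshed *ratio* need not be monotone in budget on a finite network
  (the circle denominator grows as r²; once the whole network is reached
  the ratio necessarily falls), which is why the monotonicity guarantees —
  and tests — for budget and speed are on reached length and catchment
  area, while waits are guaranteed (and tested) monotone for all three
  metrics.
- Destination sampling is uniform by length; population- or land-use-
  weighted sampling is future work.
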