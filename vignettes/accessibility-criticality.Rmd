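---
title: "User-centric accessibility, road criticality and isolation under hazard scenarios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{User-centric accessibility, road criticality and isolation under hazard scenarios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roadaccess)
```

## The model

`roadaccess` measures how easily a population reaches a system of public
service facilities (healthcare is the motivating sector) over a road
network, and how that access degrades when floods or seismic fault
exposure disrupt the network.

The city is a graph $G(V, E)$: vertices are street intersections, edges
are street segments with a length $\ell$ (m), a road class, a free-flow
speed $s$ (km/h) from a class lookup table, and a derived travel time
$t = \ell / (1000\,s/60)$ in minutes. The graph is undirected by default,
the usual abstraction for city-scale drive-time analysis; a directed mode
exists but is secondary.

Population lives on a polygon grid. Each cell's population is carried
onto sampled **origin nodes**: within a cell of population $P$ and $k$
selected origins each origin receives weight $P/k$, so cell populations
are conserved exactly. Service facilities are snapped to their nearest
network vertex and act as destinations; each carries a footprint area
$A_j$ (m²) used as a capacity/attractivity proxy.

**Facility choice (Huff model).** The probability that origin $i$ visits
facility $j$ is

$$P_{ij} = \frac{A_j / t_{ij}}{\sum_{k \in R(i)} A_k / t_{ik}},$$

where $R(i)$ is the set of facilities reachable from $i$. Note the
normalization runs over destinations: that is the only reading under
which the probabilities from one origin sum to one, which is also the
property the method's own worked examples rely on. Unreachable
facilities are removed from the choice set (probability 0); when the
choice set is empty the origin is *isolated*.

**Accessibility** of origin $i$ is the expected travel time to the whole
service system, $\sum_j t_{ij} P_{ij}$ — not the time to the closest
facility. Isolated origins carry no finite value and are excluded from
summary statistics (they are reported separately).

**Criticality** of a road segment accumulates, over every origin
$i$ (weight $w_i$) and reachable facility $j$, the contribution
$\alpha \, w_i \, P_{ij}$ along every edge of the shortest path
$i \to j$ — a population- and preference-weighted edge betweenness.
$\alpha$ is a per-service-type importance factor supplied by the analyst
(default 1 for every type; the methodology leaves its values to
policymakers). Scores are ranked descending (ties by edge id) and a
min–max scaled version over nonzero-score edges is provided for display.

**Isolation** is the total population weight at origins from which no
facility is reachable. A literal reading of the isolation sum over all
destinations would count one origin once per unreachable facility; the
worked-example behaviour ("the population of the cut-off node becomes
isolated") fixes the operative definition used here: an origin counts
exactly once, iff *all* facilities are unreachable.

## Hazard scenarios

A hazard layer is a set of footprints: flood polygons with a depth (cm),
or fault lines / fault polygons with a return-period label. An edge is
*affected* when its geometry (stored shape, else the straight chord)
touches a footprint; boundary contact counts. Effects follow the rule
object:

| parameter | default | meaning |
|---|---|---|
| `rho` | 3 | speed divisor on penalized edges |
| `penalize_cm` | 5 | flood depth above which (strict) speed is divided by `rho` |
| `disrupt_cm` | 15 | flood depth at/above which (inclusive) the link is disrupted |
| `fault_buffer_m` | 500 | all links within this planar buffer of a fault line are disrupted |

The default `rho = 3` reflects observed congestion friction coefficients
of roughly 0.4–0.5 (speed roughly halved under heavy congestion), taken
as a conservative proxy for driving through shallow water: affected
links run at one-third of free-flow speed. Threshold boundary reads are
deliberate and documented: exactly 5 cm does *not* penalize ("depths
over 5 cm"), exactly 15 cm *does* disrupt.

Disruption is modelled as infinite travel time rather than edge
deletion, so disrupted segments remain addressable in criticality
reports. Compound scenarios apply several layers at once: per edge the
most severe status wins (disrupted > penalized > intact), and an edge
penalized by several layers is penalized once with the largest
applicable `rho`. Nothing in the method's source examples indicates
multiplicative stacking, and single application is the conservative
choice. Consequently disrupted sets of compound scenarios are exactly
the union of the per-layer disrupted sets, travel times never decrease
under any scenario, and removing all layers restores baseline times
bit-for-bit (the baseline network is never mutated).

For reporting, per-hazard results can additionally be aggregated:
criticality by elementwise sum or max, accessibility only by max (the
expected time under the worst constituent hazard; summing expected
times has no interpretation).

## Origin sampling

Five strategies create the origin subsample; percentages round up with
a minimum of one origin per cell containing at least one node, so no
populated cell silently loses representation:

* `FIXED_GRID_1KM` — nearest network node to each vertex of a
  1 km × 1 km lattice covering the network bounding box.
* `CELL_CENTROIDS` — nearest in-cell node to each cell centroid. The
  search is restricted to the cell's own nodes so each cell's population
  stays on its own territory; cells without nodes contribute no origins
  (reported), consistent with the other cell-driven strategies.
* `NEAREST_10PCT` — per cell, the 10% of in-cell nodes Euclidean-closest
  to the centroid node.
* `RANDOM_10PCT` / `RANDOM_5PCT` — per cell, a seeded uniform sample of
  10% / 5% of in-cell nodes. Each cell draws from its own seed
  substream, so results do not depend on cell order and are reproducible
  bit-for-bit under the same seed.

A node lying exactly on a cell boundary belongs to the first covering
cell in input order (boundary-inclusive containment test) — an arbitrary
but deterministic rule, stated so runs are reproducible.

## Routing and tie-breaks

Travel times are Dijkstra shortest paths weighted by edge travel time
(igraph's implementation). Where several paths tie, the package commits
to the lexicographically smallest node-id sequence: after computing
distances from the origin and to the destination, a greedy walk over the
shortest-path DAG picks at each step the smallest-id successor
consistent with the total distance (floating-point equality at absolute
tolerance $10^{-9} \cdot \max(1, t)$ minutes). Criticality imputation
uses exactly the same walk, so reported times and imputed paths are
always mutually consistent and runs are reproducible across platforms.
Edge travel times are strictly positive, so the walk cannot cycle.

An origin co-located with a facility would give $t = 0$ and an infinite
Huff weight; travel times are floored at 0.1 min inside the choice
model, which preserves near-certain choice of the co-located facility
without infinities. The floor is configurable (`t_floor_min`).

## Subgraph partitioning

For large cities the full origins × destinations Dijkstra matrix is the
bottleneck. The partitioning scheme assigns every node within network
distance $\lambda$ km (edge length, not Euclidean — an "influence
radius" on a road network is naturally a graph distance; a Euclidean
variant would ignore rivers and ring roads) of a facility to that
facility's subgraph, then repeatedly merges subgraph pairs sharing at
least $\delta$ of their nodes, with the overlap measured against the
smaller subgraph, until no pair crosses the threshold.

Travel times to a facility of the origin's own subgraph are exact; for
an external facility $j$ the trip is composed as
$t(i \to g) + t(g \to j)$ where the gateway $g$ is the time-nearest
facility in the origin's subgraph and facility-to-facility times are
precomputed once on the full network. Composed entries are upper bounds
on the exact times, with equality when origin, gateway and destination
lie on one shortest path. Two open interpretation points are fixed as
follows: when a subgraph holds several facilities the gateway is the
time-nearest one (the natural generalization of the single-facility
example), and "exact local Dijkstra" is realized as a full-network
Dijkstra restricted to the subgraph's own destination set — the
complexity reduction comes from shrinking the destination set, and
restricting the *graph* instead could overestimate whenever a shortest
path briefly leaves the λ-ball. Origins outside every subgraph are
flagged out-of-coverage and get all-infinite rows rather than silently
wrong values.

## Scenario comparison

Two scenarios over the same origin set are compared by:

* **Jensen–Shannon divergence** between the two accessibility
  distributions, computed on a shared equal-width histogram (default 256
  bins spanning the pooled finite range) in natural-log base. Binning
  and base are not canonical anywhere; both are configurable, and the
  package's tests assert only the identities JS = 0 for identical
  distributions and JS ≥ 0 — never any city-specific value.
* the **fraction of origins whose top-choice facility changed**
  (argmax of the Huff row); origins isolated in either scenario are
  counted separately, not in the fraction.
* the **preference-shift graph**: an edge $a \to b$ weighted by the
  number of origins switching their top choice from $a$ to $b$.
* mean time (and, when path lengths were computed, expected distance)
  deltas over origins finite in both scenarios.
* a **population-share table** of access times in hour bins
  [0, 1), [1, 2), [2, 3), [3, 4), ≥ 4, plus an unreachable share; the
  shares are population-weighted and always total 100%.

## The synthetic-city generator

`generate_city()` emulates the structural features the method needs —
a connected street graph with two road classes (arterials every third
grid line at 60 km/h, local streets at 30 km/h), a tiling population
grid with uniform 100–1000 inhabitants per cell, and a handful of
facilities with lognormal footprint areas (log-mean `log(2000)` m²,
log-sd 0.5, a plausible spread from clinics to hospitals) — on a
rows × cols lattice with 500 m spacing by default. `generate_hazard_band()`
adds flood rectangles or straight faults whose affected edge sets are
predictable from geometry. `demo_city()` is a hand-coded 11-node city
with two facilities, four population cells and overlapping flood/fault
footprints; it reproduces the topology and hazard incidence of the
method's illustrative example (its exact coordinates are not published,
so fixture-based tests assert only topological and relational facts).

What the generator does **not** emulate: realistic road-class mixtures,
one-way systems, bridges/tunnels (non-planar adjacency), correlated
population–facility placement, raster population surfaces, and
empirically calibrated hazard fields. Passing tests on synthetic cities
therefore demonstrate correctness of the algorithms and their
invariants, not predictive validity for any real city.

## Numerical choices and degenerate inputs

* Geometry is purely planar; inputs must share one projected metric CRS.
  Containment is even-odd and boundary-inclusive; segment intersection
  treats touching as intersecting (tolerance $10^{-9}$ m, scaled).
* Fault buffers: the affected test uses the exact segment-to-polyline
  distance (≤ radius); the exported buffer polygon discretizes each cap
  with 32 segments per semicircle (area error < 0.1%).
* Snapping ties go to the smallest node id.
* Networks need not be connected; unreachability is encoded as +Inf
  end-to-end and never raises.
* Cells with zero population produce zero-weight origins; cities with
  zero facilities are valid and make every origin isolated.
* Self-loops and parallel edges are rejected at construction.

## Test problem sizes

The test suite exercises exact oracle equivalence (Floyd–Warshall on
random graphs up to 50 nodes; exhaustive path-enumeration criticality on
graphs of ~10 nodes), the partition upper bound on twenty 25-node
cities, monotonicity/reversibility across random hazard bands, and the
worked-example identities on the demo city. These sizes keep the full
suite under a minute while covering every code path; all generators are
seeded, so failures reproduce deterministically.

## Known limitations

* No congestion, time-of-day effects, turn penalties or multi-modal
  routing: times represent free-flow driving, and the speed table is the
  only lever for calibration.
* Hazard maps act as binary/thresholded utility-loss proxies; there are
  no fragility curves or probabilistic hazard sampling.
* The Huff attractivity uses footprint area only; richer capacity data
  (beds, staffing) would slot into the same attractivity term.
* The partitioned times are upper bounds, not exact; the gap is zero
  only under the stated alignment condition.
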