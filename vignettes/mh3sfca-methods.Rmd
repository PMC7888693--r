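---
title: "Measuring potential spatial accessibility with Huff-allocated floating catchment areas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring potential spatial accessibility with Huff-allocated floating catchment areas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcaccess)
```

## The problem and the model

Floating catchment area (FCA) methods quantify *potential spatial access* to
a service — how many opportunities (e.g. general practitioners) are in reach
per person — from three ingredients: supply sites $j$ with capacities $S_j$,
population locations $i$ with inhabitant counts $D_i$, and the travel
impedance $d_{ij}$ between them. Pairs interact only within a catchment
$d_{ij} \le d_{max}$, and interaction propensity decays with distance.

The central method in this package allocates each population's demand across
all reachable sites with a Huff spatial-interaction model before forming
supply–demand ratios. With a per-pair distance weight $W_{ij}$ it proceeds
in three steps:

$$Huff_{ij} = \frac{S_j W_{ij}}{\sum_{k:\,d_{ik} \le d_{max}} S_k W_{ik}},
\qquad
R_j = \frac{S_j}{\sum_{i:\,d_{ij} \le d_{max}} Huff_{ij} D_i},
\qquad
A_i = \sum_{j:\,d_{ij} \le d_{max}} Huff_{ij} R_j W_{ij}.$$

Because the $Huff_{ij}$ of each location sum to one, total allocated demand
equals the total covered population — the defining property that removes the
demand over-counting of binary-catchment methods, where every site within
reach counts a population's full demand. The final $W_{ij}$ factor in $A_i$
additionally penalises sub-optimally placed supply, so the population-
weighted index total satisfies $\sum_i A_i D_i \le \sum_j S_j$, with
equality exactly when all in-catchment distances are zero. $R_j$ and $A_i$
are in providers per person.

For comparison the package also implements the classic lineage under the
same input/output contract (`fca_access()`): 2SFCA (binary weights,
conserves $\sum_j S_j$ whenever every site has in-catchment demand), E2SFCA
(discrete band weights), 3SFCA (travel-time-only competition weights
$G_{ij} = W_{ij}/\sum_k W_{ik}$) and M2SFCA (distance weighting on both the
demand and the index side). These formulas follow the methods' originating
publications; the package's tests check each against an independently
written dense reference and against the limits in which the methods must
coincide (all distances zero: every method returns
$A_i = \sum S / \sum D$).

## Distance decay

The decay kernel is Gaussian, $f(d) = e^{-d^2/\beta}$. The coefficient of
friction $\beta$ is not set directly: it is derived from two interpretable
parameters, the catchment threshold $d_{max}$ (minutes) and the weight
$w_{min}$ the kernel should retain at that threshold,
$\beta = d_{max}^2 / \ln(1/w_{min})$.

* `d_max` defaults to **30 minutes** by car, the conventional longest
  acceptable travel time to primary care in densely developed regions.
* `w_min` defaults to **0.01**, a conventional floor in the FCA literature;
  it is a genuinely free parameter, so it is stored in every result's
  metadata for reproducibility.

Two weighting modes exist (`decay_params(mode = )`):

* **continuous** (default): every pair gets the kernel value at its own
  travel time — the behaviour appropriate for small-area analysis;
* **subzones**: the catchment is cut into `n_zones` equal-width travel-time
  bands (default 4) and every pair in a band gets the kernel value at the
  band midpoint (a band from 0 to 5 minutes is weighted as $d = 2.5$), the
  older discrete convention, retained for comparison and for large study
  areas. Bands are left-closed/right-open with the last band closed, so
  $d = d_{max}$ is in catchment — matching the $\le d_{max}$ condition in
  all three steps.

Weights are computed in double precision throughout; nothing is rounded
before the output stage. Only the Gaussian kernel is implemented: power,
exponential and logistic alternatives exist in the literature, but a single
well-parameterised kernel keeps $\beta$ interpretable, and the kernel enters
the pipeline only through `weight_for()`, which is the seam where another
kernel would plug in.

## Travel times

Impedance is shortest-path car travel time on a directed road network. Edge
cost is `length_m * 0.06 / speed_kmh` minutes; one-way streets are simply
edges without a reverse twin. Travel direction is population → supply
everywhere (patients travel to providers), and the same $t_{ij}$ is used in
both the population's and the site's catchment. Points are snapped to the
*nearest node* (deterministic tie-break to the smallest node id) rather
than projected onto edges: hectare-grid spacing (100 m) is below typical
edge lengths, so the approximation error is small and the behaviour is
reproducible. `od_cost_matrix()` runs Dijkstra per origin (via igraph) and
keeps pairs with $t_{ij} \le d_{max}$ (inclusive); unreachable pairs are
absent, not errors. A Euclidean fallback (`od_matrix_euclidean()`) serves
data without a network. Turn penalties, congestion and time-of-day speeds
are not modelled; coordinates must already be planar metres.

## Degenerate inputs

* A population with no reachable site gets $A_i = 0$ (zero encodes "no
  access within the catchment") and is counted in the result metadata, not
  dropped.
* A site with no allocated demand (unreachable, or only empty cells in
  reach) gets $R_j = 0$ with a warning rather than an error, so island
  sites cannot abort a regional run.
* Cells with $D_i = 0$ still receive an index — the location has access
  even if nobody currently lives there — but contribute nothing to any
  denominator.
* Zero-capacity sites are rejected at load time; co-located practices can
  be aggregated by `read_points(aggregate = TRUE)` (capacities summed).

## The synthetic study region

Real inputs of this kind — a census hectare grid, a commercial provider
registry, a cleaned OSM car network — are large and partly proprietary, so
the package generates regions with the same *structure*
(`make_scenario()`, `scenario_preset()`):

* **Demand**: 100 m cell centroids with independent Poisson counts whose
  means follow one or more exponential density peaks over a uniform rural
  floor; empty cells are dropped, reproducing the blank unpopulated areas
  of a census grid. Defaults: 10 km × 10 km, one centre with a peak of 50
  inhabitants per cell, 2 km decay length, floor 0.2 (≈ 10⁵ inhabitants).
  The monocentric exponential profile is the simplest density model that
  produces the urban/rural contrast observed in real regions.
* **Supply**: 25 sites, 80 % placed population-proportionally and 20 %
  uniformly (the uniform share creates occasional rural practices), with
  integer capacities 1–5 — the scale of single practices.
* **Network**: a lattice with 500 m spacing, speed limits drawn from
  {30, 50, 80, 100} km/h per street, and 10 % of streets one-way. One-way
  injection is repaired until the giant strongly connected component spans
  ≥ 95 % of nodes, so catchments stay meaningful.

The `two-town` preset uses a 30 km × 30 km extent with towns about 21 km
apart: two towns can only show up as two separate accessibility maxima if
their spacing exceeds the 30-minute travel scale — inside a 10 km region
everything is mutually reachable and the surface necessarily peaks once, in
the middle.

Everything is deterministic under the configured seed. What the generator
does **not** emulate: real street topology (no rings, motorways or dead
ends), demographic structure, daytime/tourist populations, and supply
beyond the region border. Passing tests on these regions therefore
demonstrate the correctness and qualitative behaviour of the methods, not
the accuracy of any real-world index value.

## Classification and reporting

Indices are mapped for presentation with empirical quantile classes
(default quintiles): boundaries use the linear-interpolation quantile
definition (R type 7), ties go to the lower class, and degenerate breaks
collapse to class 1 with a warning — the GIS convention behind such maps is
software-specific, so the package fixes and documents one. Printed
summaries truncate indices toward zero at eight decimals (the map-label
convention for these small values); CSV output always keeps full double
precision, and round trips through the CSV formats are lossless.

## Verification strategy and problem sizes

The test suite checks every step against an independent route: a dense
triple-loop reference for each of the five methods (200 random instances of
up to 30 × 20 locations, agreement within 1e−10), Floyd–Warshall for the
thresholded Dijkstra matrix (50 random directed graphs of up to 50 nodes),
closed forms for uniform-distance systems, exact Huff row normalisation
(1e−12) and demand conservation (1e−9 relative), the supply bound for the
Huff-allocated and M2SFCA variants, and the urban–rural gradient on the
seeded monocentric region (central quarter vs peripheral quarter of
locations by distance to the density centre, population-weighted). The
default monocentric region (~10⁴ populated cells, ~2.5 × 10⁵ pairs) runs
the whole pipeline in a few seconds.

## Known limitations

Border effects are not corrected: supply and demand just outside the study
area are invisible, biasing indices near the border downward. Only one
travel mode is modelled at static speeds. Absolute index magnitudes depend
on $d_{max}$, $w_{min}$ and the kernel; they rank locations and compare
regions, but no absolute value by itself defines over- or undersupply.
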