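---
title: "Climatic corridors out of Africa: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Climatic corridors out of Africa: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleocorridor)
```

## The problem

Whether, when, and along which routes hunter-gatherers could have left
Africa is, to a first approximation, a question about rainfall: the
limiting resource on the two candidate exits — the Nile–Sinai land bridge
in the north and the Strait of Bab al-Mandab in the south — is water, for
people, prey, and plants. `paleocorridor` implements the computational
chain that turns coarse palaeoclimate simulations into an answer: for each
decade of each millennium, what is the lowest precipitation (or Köppen
aridity) tolerance with which a connected path from inside Africa to
Eurasia still exists, and how does that compare with the tolerance
observed in ethnographic hunter-gatherer populations?

The chain has five computational stages, each a module of the package,
plus a synthetic-data generator that makes the whole pipeline testable
end to end with no external downloads.

## Downscaling: dynamic and classical delta methods

Coarse simulations (a 3.75° × 2.5° grid) are downscaled in two steps.

**Dynamic delta.** A small set of expensive fine-resolution snapshot
simulations (1.25° × 0.83°, nine snapshot times over the last 21 ka) acts
as a library of fine-scale correction patterns. For an analysis time $t$,
the reference snapshot $\hat t$ is the one whose global CO$_2$
concentration is closest to CO$_2$ at $t$ — CO$_2$ as a one-dimensional
index of global climate state — with ties broken toward the more recent
snapshot. Precipitation uses the multiplicative form
$$P_{\sim 1^\circ}(t) = P^{\boxplus}_{\mathrm{coarse}}(t)\cdot
  \frac{P_{\mathrm{fine}}(\hat t)}{P^{\boxplus}_{\mathrm{coarse}}(\hat t)},$$
temperature the additive analogue. $\boxplus$ is the regrid operator
(below). The multiplicative correction ratio is guarded: denominators are
floored at 0.1 mm yr$^{-1}$ and ratios capped at 100, since the quotient
is undefined in hyperarid cells and unguarded ratios would amplify noise
without bound; outputs are clipped at zero.

**Classical delta.** The second step corrects against the present-day
*observed* climatology on the ~0.5° analysis grid:
$P_{\sim 0.5^\circ}(t) = P^{\boxplus}_{\sim 1^\circ}(t)\cdot
P_{\mathrm{obs}}(0)/P^{\boxplus}_{\sim 1^\circ}(0)$. For temperature we
subtract the present-day ($t = 0$) model value, mirroring the
precipitation form: a classical delta correction is by definition anchored
at the present, and an alternative reading that anchors the temperature
correction at $\hat t$ would make the two variables inconsistent. This was
a genuinely open design point; the present-day anchor is the one under
which the constant-input identity (chain output = observations) holds for
both variables.

**The regrid operator.** $\boxplus$ must be continuously differentiable
(unlike bilinear interpolation) while not overshooting the local data
range (unlike bicubic). We implement it as a tensor-product
Fritsch–Carlson shape-preserving cubic Hermite (PCHIP) scheme, vectorised
over whole fields. This is the contract that matters — C$^1$ smoothness,
exact reproduction of constant and (bi)linear data, and no new extrema —
rather than any particular named interpolant; the test suite checks the
tensor scheme against an independent single-series PCHIP implementation
(`pracma::pchip`). Coordinates are kept as supplied (validated to
$[-180°, 360°)$ with strictly monotone axes) rather than normalised to
$[0°, 360°)$; the analysis window 15–70°E never approaches the
antimeridian, and renormalising would break axis monotonicity for grids
spanning 0°.

**Land configuration.** A node is land at time $t$ iff its present-day
elevation strictly exceeds the sea level $s(t)$ (with $s(0) = 0$), so
masks for lower sea levels nest around masks for higher ones. Nodes below
present sea level but exposed at time $t$ carry no delta-method value
(there is no observed climatology under water); they are filled by
inverse-distance weighting from the $k = 4$ nearest present-day land
nodes with power 2 and great-circle distances. The donor rule and
exponent are unspecified upstream; these are standard defaults, exposed
as arguments.

All great-circle distances in the package are haversine distances on a
sphere of radius 6371.0088 km.

## Decadal variability

Each millennium's 30-year climatological normal is refined into 100
decadal fields using a 1000-year annual simulation series. For decade
$d \in \{1,\dots,100\}$ the precipitation scaler is the ratio of the
decadal mean to the mean of the 30-year window of decades
$d-1, d, d+1$; temperature uses the difference of means. Two conventions
here are decisions, not inferences:

* **Means, not sums.** Written as a quotient of a 10-term sum and a
  30-term sum, a constant series would give 1/3; only the ratio-of-means
  convention makes the scaler a pure anomaly (1 for constant data) that
  preserves scale when multiplied into a 30-year normal.
* **Clamped edge windows.** For $d = 1$ and $d = 100$ the 30-year window
  would leave the millennium; since annual series of successive millennia
  are simulated independently and their ends do not coincide, stitching is
  not meaningful, and the window is clamped to the available years (years
  1–20 and 981–1000 respectively).

The scaler millennium for an analysis time outside the annual-series
coverage is chosen by the same CO$_2$ matching as the snapshot reference
time. Because decadal windows overlap and edge windows clamp, the mean of
the 100 decadal fields is not algebraically identical to the normal; on
smooth synthetic series it agrees to well within 15%, which is the bound
the tests assert.

The Köppen aridity index is $A = P/(T + 33)$ with $P$ in mm yr$^{-1}$ and
$T$ in °C; it is undefined for $T \le -33$ °C and the package raises an
error there rather than returning a negative index.

## Corridor analysis

The analysis grid is quasi-hexagonal with a target internode spacing of
~55 km (~0.5°) over 15–70°E, 5–43°N; two nodes are adjacent iff their
great-circle distance is at most the grid's maximum internode spacing. We
build it as offset rows (hexagonal packing) with in-row spacing scaled by
$1/\cos\varphi$, rather than by subdividing an icosahedron: only the
spacing and the hex topology are normative for the analysis, the row
lattice meets both (median neighbour distance within 10% of target,
~6 neighbours per interior node), and it is simpler to reason about and
to test. At desk scale the package defaults to 140 km spacing (~1400
nodes over the window, a ~46 × 30 arrangement); all algorithms are
spacing-agnostic.

A node is *suitable* at tolerance $p$ if it is land and its climate value
is $\ge p$ (inclusive). Routes modify this set:

* the **northern** analysis removes the strait zone, the **southern**
  analysis removes a Sinai box, so each route's connectivity is measured
  in isolation; the exact removed cells are configurable polygons since
  only their function (severing the other passage) is prescribed;
* on the southern route (and the unrestricted union), nodes within
  ~40 km of the strait centre (default 43.4°E, 12.6°N) are exempt from
  both sea-level and climate constraints — the strait is assumed
  crossable; the zone radius is never narrower than the grid's maximum
  internode spacing, since a zone that captures no node and severs no
  edge would be a no-op on a coarse grid;
* the Nile delta box (default 30.5–32.5°E, 29.5–31.6°N) is suitable at
  all times, for rivers are not rainfall.

Connectivity from the start node (32.6°E, 10.2°N) to the exit region
(λ > 65°E or φ > 37°N) is a breadth-first search on the suitability
subgraph. The critical tolerance is found by bisection from the bracket
[0, 1000] mm yr$^{-1}$ (aridity: [0, 4.0]): ten iterations, then the
midpoint of the final bracket, which is within
$1000/2^{11} < 1$ mm yr$^{-1}$ of the exact value. The exact value is
also computable directly — it is the maximin (widest-path bottleneck)
value, obtained by a binary threshold sweep over the sorted distinct node
values — and the package carries both so each can check the other. If no
path exists even at tolerance 0 the result is a `blocked` sentinel rather
than a degenerate bisection. Windows of opportunity are summarised as the
percentage of a millennium's 100 decades with a connected path at each
tolerance.

## Tolerance threshold

The hunter-gatherer tolerance is estimated from an ethnographic table as
the minimum precipitation (or aridity) over populations *not* flagged as
freshwater-adjacent — the level below which no rainfall-constrained
population is recorded. The flag is an input, not a geospatial inference:
the excluded populations are identified by prior knowledge, not by a
rule this package could reproduce. A percentile parameter (default 0,
the minimum) is provided for sensitivity analyses. On the real
ethnographic data this statistic lands near 90 mm yr$^{-1}$ and a Köppen
aridity of about 1.7; those numbers depend on external data and are
treated as an external validation, not a unit test.

## Strait crossing width

From a high-resolution elevation/bathymetry raster and a sea level $s$,
cells with elevation $> s$ are partitioned into 8-connected landmasses
(8-connectivity avoids spurious splits at diagonal contacts; the
convention upstream is unstated). The complete graph on landmasses is
weighted by the minimum great-circle distance between boundary-cell
centres, and the crossing width is the minimax-path value between the
African and Arabian components (largest hop minimised, stepping-stone
islands allowed), computed via the minimum spanning tree. Distances are
between cell centres, so results carry an error of up to about one cell
size; tests use that tolerance.

## The synthetic world

`make_world()` generates every input the pipeline consumes, from a single
seed, with planted structures whose downstream answers are known:

* smooth band-limited random fields (sums of low-order cosine modes with
  seeded coefficients) for precipitation, temperature, elevation, and
  observational patterns — smooth so that interpolation accuracy is
  meaningful; precipitation clipped at 0, temperature unbounded;
* a coarse series at 1-ka steps, fine snapshots at nine times, a
  1000-year annual series per analysis millennium (AR(1) interannual
  variability, multiplicative for precipitation), and a present-day
  observed climatology;
* an oscillating sea-level curve with $s(0) = 0$ (default amplitude 120 m
  over a 20-ka period) and a smooth positive CO$_2$ curve;
* two planted corridors — northern through the Sinai box, southern
  through the strait zone — with configured bottleneck values per
  millennium (defaults 100 + 8t and 130 + 6t mm yr$^{-1}$): along each
  path values ramp up from a single bottleneck cell, and everything off
  the paths is capped at a barrier value (20 mm yr$^{-1}$), so the
  maximin value of each route equals its planted bottleneck exactly and
  the unrestricted analysis equals their maximum;
* a strait whose cross-section is a flat trench (half-width 1.2 km at
  −110 m) with flanks rising at 12.5 m per km, giving the closed-form
  gap width $2\,(1.2 + (s + 110)/12.5)$ km for $s \ge -110$ m and a land
  bridge below — about 20 km at present sea level and 4 km at a 100 m
  lowstand, the range reconstructed for the real strait;
* a population table with a planted precipitation floor (90 mm yr$^{-1}$)
  attained exactly once, residence temperatures near 20 °C arranged so
  the same population attains the aridity floor
  $90/53 \approx 1.70$, and three flagged freshwater-adjacent outliers
  below the floor.

What the generator does *not* emulate: real HadCM3 spatial statistics,
seasonality, monsoon dynamics, sub-decadal variability, isostasy, or real
geography — the synthetic window is mostly land with smooth basins.
Passing tests therefore demonstrate that the algorithms are correct and
internally consistent, not that any particular palaeoclimate
reconstruction is right.

## Worked example

```{r example, eval = FALSE}
world <- make_world(seed = 1)

# hunter-gatherer thresholds from the synthetic ethnographic table
estimate_threshold(world$populations, "precip")   # 90
estimate_threshold(world$populations, "aridity")  # 1.698 (= 90 / 53)

# critical precipitation tolerance, northern route, millennium 0
land <- land_mask(world$elevation, world$sea_level, 0)
rn <- route_nodes(world$routes$northern, world$hex)
critical_threshold(world$normals[["0"]]$precip, world$hex, land, rn)$p_crit
# ~100.1, against a planted bottleneck of 100

# strait width through time
head(crossing_series(world$bathymetry, world$sea_level, 0:9), 3)
```

## Numerical choices and limitations

* Bisection depth is fixed at 10 iterations; the bracket width after $k$
  iterations is exactly $(\hat p_0 - \check p_0)/2^k$.
* Threshold comparisons are inclusive ($\ge p$); land is strict
  ($E > s$). Both follow the definitions of the suitability set and land
  mask.
* The ratio guard (floor 0.1 mm yr$^{-1}$, cap 100) means the
  multiplicative identities (e.g. dynamic delta at $t = \hat t$ returning
  the snapshot exactly) hold wherever the reference field is above the
  floor; in hyperarid cells the guard deliberately trades exactness for
  boundedness.
* Default problem sizes (8 millennia, 140-km grid, 1000-year annual
  series, 0.01° strait raster) were chosen as the smallest sizes at which
  every planted structure is resolved by several grid cells; they are
  package defaults, and every size is configurable through
  `world_config()`.
* The package measures climatic *feasibility* of exits, not dispersal:
  no demography, no route cost, no seafaring model — only existence and
  bottleneck values of connected corridors.
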