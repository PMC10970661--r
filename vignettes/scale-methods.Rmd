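---
title: "The SCALE accessibility index: model, assumptions and design choices"
author: "scaleaccess"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The SCALE accessibility index: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scaleaccess)
```

## The problem

Access to primary care is usually summarized one administrative unit at
a time: a provider-to-population ratio per municipality, or a two-step
floating catchment area (2SFCA) score at a fixed travel-time threshold.
Both choices hide within-unit heterogeneity and force a single facility
type and a single scale. The SCALE index scores accessibility at the
finest spatial unit available — the residential-area point where
population actually sits — for a whole catalogue of facility types, and
only then aggregates upward, so the scale of reporting becomes an
explicit, auditable choice rather than a constraint of the method.

## The model

Let $t_{ij}$ be the travel cost (minutes by default) from residential
area $i$ to facility $j$, $P_i$ the population of area $i$, and $m_j$
the number of professionals at facility $j$. For each facility type $k$:

**1. Catchment radius per census unit.** For each IRIS $u$,

$$R_{uk} = \max_{i \in u} \; \min_{j \in k} t_{ij},$$

the longest travel time to the *nearest* type-$k$ facility among the
unit's areas. This is the smallest radius that guarantees every
resident of the unit one reachable facility. Using the unit-level
maximum (rather than a per-area radius) makes all areas of an IRIS
comparable: they face the same threshold, and a remote hamlet widens
the catchment for its whole unit.

**2. Potential accessibility area (ZAP).**
$Z_{ik} = \{\, j \in k : t_{ij} \le R_{u(i)k} \,\}$. The threshold is
inclusive, so the facility that defines the radius is itself a member
and the set is never empty. Ties in nearest-facility costs are broken
by the lexicographically smallest facility id; all downstream output is
therefore deterministic.

**3. Pressure.** Demand on a facility is estimated by a travel-cost
Voronoi assignment: each area's entire population is assigned to its
single nearest type-$k$ facility, and

$$\text{pressure}_j = \frac{\sum_{i : j = \mathrm{nn}(i)} P_i}{m_j}.$$

Each person is counted exactly once, so per type the assigned
population sums to the total population (a conservation law the test
suite asserts). The assignment uses the same travel metric as the OD
matrix rather than geometric polygons, which keeps the "mosaic"
consistent with network travel times. Pressure is computed on the full
facility set of the type, not restricted to any ZAP: it is a property
of the supply point, not of the demand point asking about it.

**4. Potential accessibility distance (PAD).**

$$\mathrm{PAD}_{ik} = \frac{\sum_{j \in Z_{ik}} w_j\, t_{ij}}
                           {\sum_{j \in Z_{ik}} w_j}.$$

The weights take facility availability into account. The package's
default is $w_j = \text{pressure}_j$: congested facilities dominate the
mean, so the PAD reflects the distances the population is effectively
drawn into. The direction of this weighting is the one genuinely open
modeling choice in the pipeline, so the opposite reading
($w_j \propto 1/\text{pressure}_j$, availability-proportional) is
exposed as `weight_mode = "inverse_pressure"` rather than hard-coded;
every structural property (bounds, homogeneity, gradient recovery)
holds under either mode. If all member pressures are zero the
unweighted mean is used — this avoids 0/0 and preserves the invariant
$\min_j t_{ij} \le \mathrm{PAD}_{ik} \le \max_j t_{ij}$ over the ZAP.
In inverse mode, a zero-pressure member receives the largest inverse
weight present in the set (it is maximally available).

**5. Standardization and combination.** PAD distributions are strongly
right-skewed, so plain z-scoring would not deliver a "reduced centered
normal" variable. Each type's PAD vector is instead transformed by the
rank-based Blom score $\Phi^{-1}\!\big((r - 3/8)/(n + 1/4)\big)$ on
midranks, which is strictly monotone in the PAD, has mean zero by
symmetry, and has a sample SD matching the theoretical Blom SD for
distinct inputs. (`normalization = "zscore"` preserves the simpler
reading.) The index is the signed equal-weight sum

$$\mathrm{SCALE}_i = s \sum_k w_k z_{ik}, \qquad s = -1,$$

so shorter pressure-weighted distances yield larger SCALE values:
decile 1 (the top decile) is the best-served tenth of areas. Both the
sign and the per-type weights are configuration, since only the
convention — not a fitted weight vector — is defined by the method.

**Deciles.** Labels are assigned from the top by rank:
`ceiling(rank * 10 / n)` on descending values, which reproduces
empirical-decile slicing for distinct values and gives tied values the
better (lower-numbered) label of their boundary side. An all-constant
vector collapses to a single class with a warning.

## Travel costs

Straight-line distance at a constant speed (default 50 km/h) is the
fallback metric; the recommended metric is shortest-path travel time on
a road network (igraph Dijkstra over an edge list, bidirectional edges
unless flagged one-way). Points are snapped to the nearest network
node; the snap distance is checked against a configurable maximum
(default 5000 m) and snap legs cost nothing by default, the usual
convention for dense networks (an option prices them at a walk/drive
speed). Time-of-day traffic, turn restrictions and non-car modes are
out of scope.

For large runs, areas are processed by region: candidate facilities
are those in the region plus neighboring *departments* for proximity
types (GPs, nurses, physiotherapists, dentists, pharmacists) or
neighboring *regions* for tertiary types (emergency departments,
maternity units, ...). Adjacency is supplied as a table rather than
computed from polygons, keeping the package geometry-light. Facility
layers carry no unit identifiers, so each facility inherits the
commune/region of its nearest residential area. Chunking is an
optimization, not a reachability rule: a region whose neighborhood
contains no facility of some type falls back to the full national set
for that type, with a warning, so chunked and unchunked runs agree
wherever the candidate sets cover the true nearest facility.

## Aggregation

Area-level values aggregate to IRIS, commune or region by min, max,
mean, or population-weighted mean; a unit with zero total population
falls back to the plain mean with a warning. Every (level, criterion)
version is re-categorized by its own deciles, and versions are compared
by the percentage of units with identical decile labels. Note that
aggregating means of means does not commute with direct aggregation
(population-size confounding), which is precisely why the criterion is
an explicit argument.

## The synthetic generator

`synth_geography()` emulates the *structure* of the national inputs the
method was designed for: clustered (settlement-like) or uniform area
point patterns; lognormal populations (right-skewed like real
settlement sizes; defaults `meanlog = 4`, `sdlog = 1`, median ≈ 55
persons per area); a six-type facility catalogue whose per-area
densities fall from GPs (0.08 per area) to dentists (0.035) with one
sparse tertiary type (0.008), placed uniformly or biased toward
population; a grid road network with per-edge speeds drawn in
±20% of a 50 km/h base; and a nested rectangular partition for
regions → communes → IRIS, with rook adjacency. In the synthetic
hierarchy the commune layer doubles as the department layer for the
proximity-range neighborhood rule. Everything is deterministic under
the configured seed.

What it does **not** emulate: real road topology (grid only), zoning
or land-use constraints on settlement, correlated facility co-location
(clinics clustering in centers beyond population bias), and demand
structure by age or sex. Passing tests on this generator therefore
demonstrates the correctness and invariances of the computation — not
empirical validity on any real territory.

`synth_gradient()` plants known structure — a dense city cluster
holding most facilities and a sparse rural margin — and labels every
area, so an end-to-end run can be checked against ground truth: over
repeated seeds the city group's median SCALE must exceed the rural
group's under both weight modes. This ordering check is the package's
strongest end-to-end test.

```{r gradient}
g <- synth_gradient(seed = 1)
fit <- scale_index(g$areas, g$facilities)
tapply(fit$results$scale_value, g$areas$zone, median)
```

## Numerical choices and degenerate inputs

* Radius thresholds are compared with `<=`; nearest ties break by
  facility id; decile ties take the better label. All three choices
  exist to make output reproducible and order-independent
  (permuting input rows permutes output rows identically).
* PADs scale exactly linearly with a uniform rescaling of travel
  costs (radii, ZAPs and the Voronoi assignment are rank-based and
  unchanged), and are invariant to a uniform positive rescaling of
  pressures; both properties are asserted to ~1e-9.
* A constant PAD vector (e.g. facilities co-located with every area)
  carries no ordering information and `normal_scores()` refuses it
  rather than returning zeros silently.
* Coordinates must be planar (meters). Input that looks like
  lon/lat degrees is rejected outright instead of being reprojected;
  the package deliberately contains no CRS machinery.
* The test suite and the acceptance script use fixtures of 30–1000
  areas and networks of up to a few hundred nodes; each run completes
  in seconds while still exercising every stage, including region
  chunking, at realistic relative densities.

## Known limitations

* The pressure-weight direction is a modeled choice (see above), not
  an assertion about any published calibration.
* One radius per (IRIS, type) is the default; a single per-IRIS radius
  across all types is available via `radius_scope = "global"` for the
  coarser reading of "the longest travel time to the nearest facility".
* Pressure ignores competition between overlapping ZAPs beyond the
  single nearest-facility assignment, and demand is raw population —
  no age/sex weighting, no part-time adjustment of professionals.
* Travel is car-only, traffic-free, and symmetric unless one-way edges
  are declared.
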