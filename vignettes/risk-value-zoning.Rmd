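---
title: "Risk-value zoning of national parks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Risk-value zoning of national parks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parkzoning)
```

## The problem

Many protected areas in developing countries follow a "one park, two zones"
model: a strictly protected **core area** and a surrounding **general control
area** where residents live and work. Zoning at that coarse level says little
about *where inside the core* ecological risk concentrates, or *where inside
the general area* ecosystem services are valuable enough to anchor
ecotourism. This package implements a quantitative refinement: it scores
ecological risk per assessment unit over the core, monetizes ecosystem
services per unit over the general area, and intersects the two graded
surfaces into four management zones —

* **CHR** — core, high ecological risk: priority protection and restoration;
* **CLR** — core, low ecological risk: maintain and monitor;
* **GHE** — general, high ecosystem service value: value conversion
  (ecotourism, education);
* **GLE** — general, low ecosystem service value: livelihood and resettlement
  space.

The only required inputs are a categorical land-use raster, a core/general
zone mask on the same grid, and a class catalog.

## The risk model

The park is tessellated into square assessment units (default **400 m**, a
common landscape-sampling grain of 2–5 times the mean patch size; a ~500 km²
park yields roughly 3,100–3,700 units). For unit $k$,

$$\mathrm{ERI}_k = \sum_i \frac{A_{ki}}{A_k} \, R_i, \qquad R_i = \hat F_i \, S_i,$$

where $A_{ki}$ is the area of land-use class $i$ inside the unit, $A_k$ the
unit's in-park area, $\hat F_i$ the (normalized) ecological vulnerability
rank of the class, and $S_i$ its landscape disturbance index

$$S_i = a\,C_i + b\,N_i + c\,D_i, \qquad (a, b, c) = (0.6,\ 0.3,\ 0.1),$$

built from three configuration metrics computed over the core landscape:

* fragmentation $C_i = n_i / A_i$ (patches per km²),
* isolation $N_i = \dfrac{A}{2 A_i} \sqrt{n_i / A}$,
* dominance $D_i = (M_i + L_i)/2$ with $M_i = n_i / \sum_j n_j$ and
  $L_i = A_i / A$.

Here $n_i$ is the number of patches of class $i$ (8-connected by default,
the FRAGSTATS convention; 4-connectivity is a switch), $A_i$ its area and
$A$ the landscape area, all in km². The isolation formula is kept in one
small function (`isolation_index`) because variants of this index circulate
in the literature; swapping in an alternative reading is a one-line change.

Vulnerability ranks for the default 12-class legend run from 1 (building
land — already converted, nothing left to lose) to 12 (bare land — most
fragile), with forests low and water/wetland high. By default ranks are
normalized by their catalog sum ($\hat F_i = F_i / 78$), which puts ERI on a
convenient 0–0.5-ish scale; because this is a uniform rescaling it cannot
change unit orderings, Jenks grade memberships, or the zoning — a property
the test suite asserts. Raw ranks are available via `normalize_F = FALSE`.

Two deliberate scope choices:

* **Landscape-global metrics.** $n_i, A_i, M_i, L_i, A$ are computed once
  over the whole core landscape, so $R_i$ is one number per class and
  per-unit variation comes entirely from composition $A_{ki}/A_k$. This is
  the literal reading of the index definitions. (A per-unit metrics variant
  is a natural extension but is not the default.)
* **No min–max normalization of $C, N, D$** before weighting, again the
  literal form; `normalize_cnd = TRUE` provides the common alternative.

## The service-value model

Over the general control area the package applies the equivalent-factor
method. Each class belongs to one of 8 valuation groups (the four forest
types and, by default, garden plot collapse into "forest land"; a switch
maps garden plot to cropland instead). A group's row of dimensionless
equivalence factors spans 11 service subcategories in four categories
(provisioning, regulating, supporting, cultural). Money enters through one
scalar, the **unit equivalent value** (default 231,427 yuan km⁻² per
equivalence factor, the "one seventh of average food price" convention,
supplied from local statistics), giving per-class coefficients
$VC_i$ in 万元 km⁻² (RMB 10⁴). Then

$$\mathrm{ESV}_k = \sum_i A_{ki} \times VC_i.$$

The shipped equivalence table is a *documented default in the style of the
Chinese national per-unit-area equivalent tables* (forest row sums to ≈23
equivalents; water is the most valuable group through hydrological
regulation; building land carries zeros). Park-specific tables replace it
wholesale through the YAML catalog; all entries are required to be
nonnegative, so published tables with negative paddy water-supply terms
must be clamped or re-expressed before use. Category values are computed
from category-restricted coefficient columns and therefore partition
$\mathrm{ESV}_k$ exactly; per-unit sums are accumulated in a fixed
class-code order so totals are independent of raster traversal order.

The report layer is the only place rounding happens (half-even, 2 dp), and
converts totals to RMB million for presentation.

## Surfaces, grades, zones

Unit centroid values are interpolated by **ordinary kriging**: an empirical
Matheron semivariogram (12 lags to half the region diameter), a weighted
least-squares fit of a spherical/exponential/Gaussian model (weights = pair
counts; a fixed deterministic grid of starts for the bounded optimizer), and
local-neighborhood prediction (16 nearest samples) with the unbiasedness
constraint $\sum w = 1$. Kriging runs **per zone** — ERI strictly inside the
core, ESV strictly inside the general area — and never blends across the
boundary, because the two fields measure different things for different
management questions. Sliver units (in-park area below 25% of a full unit,
configurable) are excluded from the sample set but still receive predictions
and zones. Singular systems fall back to a larger neighborhood and finally
to inverse-distance weighting with a warning.

Each surface is classified into **5 grades by exact Fisher–Jenks** dynamic
programming (minimum within-class sum of squares). Breaks are reported as
the minimum of each upper class, and values equal to a break join the upper
class — the half-open convention in which grade intervals print as
$b_1 \le v < b_2$. For inputs beyond 4,000 values the DP runs on 4,000
deterministic order statistics, the standard practice of GIS classifiers;
below that it is exact (and is verified against an exhaustive-partition
oracle in the tests).

The four-zone map uses data-driven cuts by default: the **first ERI break**
(so CHR = ERI grades II–V) and the **second ESV break** (so GHE = ESV grades
III–V). These choices transfer the *method* of cutting — both cuts are
themselves Jenks breaks of the study data — rather than any fixed number;
fixed numeric cuts are available in the config for reproducing a specific
study's thresholds. Zoning is performed per cell on the kriged surfaces, so
zone maps are spatially continuous; grading raw unit values instead is
possible by passing a unit field to `apply_grades()`.

## The synthetic landscape generator

Real classified land-use rasters for protected areas are rarely
redistributable, so the package ships a first-class generator rather than
canned fixtures. `generate_landscape()` implements **modified random
clusters**: Bernoulli($p$) site percolation, 4-connected clustering,
cluster-to-class assignment by area quotas (matching a target composition),
one majority-vote dilation pass, and i.i.d. fill of the remainder. The
clumping parameter $p$ controls fragmentation monotonically — mean patch
size rises with $p$ (tested across seeds) — which matters because
fragmentation is exactly the property the risk index responds to; a plain
noise field would not exercise $C_i$ or $N_i$ meaningfully.

Defaults mirror the study conditions the pipeline targets: a 240 × 240 grid
of 100 m cells (576 km² extent), a contiguous park footprint of ≈87% of the
extent (≈500 km²), a core share of 51.82% (the published core/general split,
hit to within the generator's ±1% contract by eroding the footprint to a
depth threshold and topping up the final ring deterministically), a
forest-dominated 12-class composition (58% arbor forest), clumping 0.5, and
four fragmentation hot-spots (cultivated/garden/bare scatter) near the
core/general boundary. At the 400 m unit size this yields ≈3,100 assessment
units, matching the scale of the study design. The full default pipeline
runs in well under a minute on one CPU; the test suite uses smaller rasters
(up to 80 × 80 for end-to-end runs, 200 × 200 for generator contracts)
chosen as the smallest sizes at which the asserted statistics are stable.

What the generator does **not** emulate: terrain and elevation gradients,
anisotropic land-use patterns along valleys or roads, registration error,
classification noise, and multi-temporal change. Passing tests therefore
demonstrate correctness of the *computations* and the stated statistical
contracts of the generator — not that any particular real park will show
the same grade or zone proportions.

## Numerical choices and degenerate inputs

* Areas are exact cell counts × cell area; tessellation conserves in-park
  area exactly (asserted at the cell-count level).
* Zone label of a boundary-straddling unit is the majority zone of its
  in-park cells; ties resolve to the core (the stricter regime).
* Classes present in an edge unit but absent from that zone's landscape
  (possible for majority-vote zone labels) carry a zero loss index and are
  recorded on the field object.
* Nodata cells break patch connectivity and contribute no area.
* Variogram fitting falls back to a pure-nugget model when degenerate; a
  pure-nugget prediction is the neighborhood mean (asserted).
* `jenks_breaks` requires at least `k` distinct values and errors otherwise,
  suggesting a smaller `k`.
* A park with no general area skips the ESV stages with an explicit message
  and still produces a CHR/CLR zoning.
* Every randomized step (generator, hot-spots, footprint wobble) flows from
  one integer seed; reruns are byte-identical, and each run writes its fully
  resolved configuration beside the outputs so every open choice is
  auditable.

## Known limitations

* The ASCII-grid dialect is the only raster interchange format; CRS handling
  is a pass-through tag, and reprojection/resampling are out of scope.
* Absolute ERI magnitudes depend on the normalization convention and on the
  catalog's ranks; only orderings, grades and zones are comparable across
  configurations.
* The default equivalence table is a literature-style stand-in; serious use
  requires the park-specific table through the catalog config.
* The isolation index is implemented in one stated reading; where a study
  used a different variant, replace `isolation_index`.
* Kriging assumes isotropy and second-order stationarity within each zone;
  strongly drifted fields would need universal kriging, which is out of
  scope.
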