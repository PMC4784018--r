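---
title: "Screening source and receptor sites for ecosystem-scale translocation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening source and receptor sites for ecosystem-scale translocation}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(estselect)
```

## The screening model

Ecosystem-scale translocation (EST) moves the topsoil, vegetation and
associated communities of a functioning ecosystem to a new site as a unit.
For EST to be worth trialling in a country, three things must coexist
there: *source* area — land of high conservation value whose climate is
projected to become unsuitable; *receptor* area — land whose climate is
projected to stay stable but whose own biota has already been lost to severe
soil degradation; and a workable road distance between the two.

`estselect` implements that screening as a deterministic geoprocessing
pipeline over four vector layers:

1. **Ecoregions**, each carrying seven climate-stability indices
   $s_1,\dots,s_7 \in [0,1]$, one per future-climate scenario (1 = complete
   overlap between present and projected climate, 0 = none). The screening
   statistic is the equal-weight mean $\bar s = \frac{1}{7}\sum_i s_i$.
   An ecoregion is *unstable* when $\bar s < 0.33$ and *stable* when
   $\bar s > 0.66$; the boundary values themselves are intermediate
   (strict inequalities). Whether the seven scenarios deserve unequal
   weights is an open question; with no stated weighting we use the plain
   mean.
2. **Biodiversity hotspots** (high conservation value).
   Source layer = (union of unstable ecoregions) ∩ (union of hotspots).
3. **Soil-degradation polygons** with ordinal severity 1–4.
   Receptor layer = (union of stable ecoregions) ∩ (union of category-3/4
   polygons); categories 1–2 contribute nothing.
4. **Country boundaries.** Both derived layers are clipped per country and
   split into connected *patches*; EST is assumed never to cross a border,
   so no cross-border merging is performed.

For each country holding both roles the pipeline reports the total source
area $A_s$, total receptor area $A_r$ (in $10^3\,\mathrm{km^2}$) and the
minimum boundary-to-boundary distance $d$ between any source patch and any
receptor patch (0 when patches touch or overlap). A factor is *limiting*
when it fails its threshold — $A \le 15{,}000\,\mathrm{km^2}$ or
$d \ge 500\,\mathrm{km}$ (strict readings of "greater than 15,000 km²" and
"less than 500 km", so a value exactly at a threshold is limiting; no
published row sits at a threshold, so this choice is untestable against the
reference table and is simply declared). Countries are categorised
`best` (no limiting factor), `distance_limited`, `receptor_limited`,
`source_limited` (one factor) or `multiple_limited` (two or more), and
ordered by the composite key *(category, $A_s$ desc, $A_r$ desc, $d$ asc,
name)*. The published reference table is not strictly sortable by any
single key; rather than replicate its printed row order we use this
deterministic key and document the divergence. Likewise its colour legend
lists "receptor areas may be limiting" twice; the bold marks show one of
those blocks is source-limited, and the package follows the bold marks.
The narrative list of best candidates in the source publication also
disagrees with its own table (it includes a source-limited country and
omits one that passes every threshold); `classify_country()` follows the
table's rules and we surface the discrepancy here rather than resolving it
silently. The shipped `reference_country_summaries()` table reproduces all
39 published rows, and `classify_country()` recovers every printed
limiting mark and exactly the 11 unflagged rows.

## Geometry engine

No polygon-overlay library is part of this package's dependency set, so the
boolean overlay is implemented here, by vertical trapezoidal decomposition:
the x-axis is cut at every vertex and every proper edge crossing; within a
slab the traversing edges stack vertically, each gap is classified by a
point-in-operand test at its midpoint, and kept gaps are merged into
trapezoids. Operands use *coverage* semantics — a point is inside an
operand when at least one of its member polygons covers it (even-odd per
polygon, so holes are honoured). Consequences that the tests rely on:

* outputs are interior-disjoint, so their summed areas are true set
  measures — overlapping hotspot or degradation polygons can never be
  double-counted, which is exactly the dissolve-then-intersect rule the
  per-country area accounting needs;
* for axis-aligned inputs with exactly representable coordinates the
  output coordinates are exact, which is what makes bit-level planar
  ground-truth tests possible;
* self-intersecting rings are repaired by even-odd interior reconstruction
  (the package's zero-buffer-equivalent rule); a feature whose repair comes
  back empty is rejected by id rather than silently accepted.

Patch extraction labels trapezoids by shared-boundary connectivity:
components sharing a boundary segment of positive length are one patch;
components touching only at a point are distinct (the adjacency distance is
0 either way, so the 500 km rule is unaffected by this convention).

## Measurement modes

Two coordinate modes separate geometry-engine error from pipeline-logic
error:

* **planar** — coordinates are km on an abstract plane; shoelace areas and
  Euclidean distances are exact, so planted fixtures can be recovered to
  machine precision (the relative tolerance asserted is $10^{-9}$).
* **spherical** — coordinates are lon/lat degrees on a reference ellipsoid
  (WGS84 by default; fixtures use the authalic sphere, $R =
  6371.007181\,\mathrm{km}$, so closed forms exist). Ring edges are read as
  geodesic arcs for areas (`geosphere`); the octant triangle and random
  spherical triangles agree with the spherical-excess (l'Huilier) closed
  form to better than $10^{-6}$ relative. Boundary distances interpolate
  edge points linearly in lon/lat and join them by geodesics, minimised by
  iterative grid refinement per segment pair; the independent check is a
  dense boundary-sampling oracle. For the sub-degree edges these layers
  carry, the two edge readings (great-circle vs lon/lat-linear) differ by
  less than any tolerance used here; the recovery tests assert 0.1 %
  on areas and 0.1 km on distances in spherical mode, and the observed
  errors are about $10^{-4}$ relative and $10^{-3}$ km.

Polygons whose edges span more than 180° of longitude are rejected with an
instruction to split at the antimeridian first; an automatic split is not
provided because silent wraparound is the failure mode that actually
corrupts global-extent areas, and an explicit error is the conservative
treatment at this package's scale.

Distances are *boundary-to-boundary*, not centroid-to-centroid: the 500 km
rule is motivated by one-day road transport between the two areas, and the
nearest boundaries are the conservative reading of that constraint. The
original workflow does not state whether its measurements were projected or
geodesic, which is why both modes exist.

## The synthetic world generator

Real counterparts of the four layers are large external datasets; the
package instead ships a generator whose outputs have *planted, analytically
known* answers, so the full pipeline is testable offline. A world is a
rows × cols grid of rectangular countries (1000 × 1000 km planar, 8° × 8°
spherical within ±40° latitude), each tiled k × k by ecoregion cells.
Defaults (4 countries, k = 4, a quarter of cells unstable and a quarter
stable, 60 % of unstable cells hotspotted and 60 % of stable cells
degraded, index noise SD 0.02) give worlds where most countries hold both
roles, categories span the spectrum, and a full pipeline run takes well
under a second — the study condition the recovery experiments (30 seeded
worlds in the acceptance run) are defined on.

Ground truth is made certain, not merely likely:

* scenario indices are the cell's class mean plus per-scenario noise
  truncated at ±3σ, and class means keep a 3σ margin from both thresholds,
  so no draw can ever flip a planted classification;
* planted source/receptor rectangles are cells shrunk by an inset that is
  an exact binary fraction of the cell, so planar truth areas and gaps are
  closed-form rectangle arithmetic with no representation error;
* spherical truth areas use the package's own spherical-excess
  quadrilateral oracle and truth distances the boundary-sampling oracle —
  both independent of the measurement engine under test;
* decoy features (hotspots over intermediate cells, category-1/2
  degradation over stable cells, severe degradation over intermediate
  cells) are planted so that the category and stability filters are
  actually exercised rather than vacuously satisfied.

What the generator does **not** emulate: realistic coastlines or hotspot
shapes, multi-country ecoregions, holes, dirty topology (except the
explicit repair tests), and degradation polygons that straddle stability
classes. Passing the recovery tests therefore demonstrates the pipeline's
arithmetic and logic, not robustness to every pathology of 1990s-era
global GIS data; the validation and repair path in `read_layer()` is the
guard there.

`world_params(frac_unstable = 0.7, frac_stable = 0.5)` and similar
infeasible settings fail loudly at construction — the generator never
silently truncates a request.

## Numerical choices

* Slab breakpoints are deduplicated at $10^{-12}$ of the coordinate span;
  zero-height gaps (coincident edges, ubiquitous with shared cell borders)
  are bridged during run merging so coincident-boundary inputs cannot
  split patches spuriously.
* Membership probes are taken at gap midpoints, never on boundaries, which
  keeps the point-in-polygon tests away from their degenerate set.
* `min_patch_distance_km()` returns exactly 0 on crossing, touching or
  containment (detected combinatorially, not numerically), and collapses
  positive values below `distance_tolerance_km` (default $10^{-6}$ km).
* Ranking thresholds are compared in km²; conversion to the printed
  $10^3\,\mathrm{km^2}$ / whole-km units happens only at serialisation.
* Ties in the ranking order fall through to an alphabetical name
  comparison, making rerun output byte-identical.

## Reproducibility surface

`run_pipeline()` consumes a single configuration (YAML-loadable) holding
either simulation parameters or the four layer paths, the thresholds, the
metric and ranking settings and one seed; it writes the derived layers,
patches, ranked table and a manifest of per-stage record counts (including
countries excluded for lacking a role). `scripts/acceptance.R` recomputes
the package's headline quantities from scratch at a given seed. The
`inst/cli/estselect.R` script exposes `simulate`, `screen`, `derive`,
`rank` and `run` subcommands over the same functions.
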