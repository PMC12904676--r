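---
title: "Methods: travel-time accessibility modelling in careatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: travel-time accessibility modelling in careatlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`careatlas` treats a country as a regular grid of square cells in a
projected, metric coordinate system. A *friction surface* assigns each
cell the time cost of motorised movement through it, in minutes per
meter; facilities are points bound to cells; and the travel time of a
cell is the least-cost path time from that cell to the nearest facility
over the grid graph. This is the standard cumulative-cost formulation
used by accessibility-mapping tools built on global friction layers.

Assumptions worth stating explicitly:

- **Square metric cells.** `cell_size_m` is a true distance. Geographic
  (degree) grids must be projected before use; the package never
  reprojects. Kilometre-scale global rasters have latitude-dependent
  cell sizes, and how a given study handled that is rarely stated — we
  make projection the caller's responsibility rather than guessing.
- **Isotropic, time-invariant friction.** No congestion, no one-way
  roads, no modal choice. Walking access is deliberately out of scope:
  the intended patient population cannot walk long distances, so only
  motorised friction is modelled.
- **Nearest-facility service.** A cell's access is fully characterised
  by its single nearest source; capacity and demand are not modelled.

## The travel-time computation

The grid graph connects each cell to its 8 neighbors (default;
4 and 16/knight-move connectivity are available for sensitivity checks).
The edge between adjacent cells $a,b$ costs

$$t(a,b) = \frac{f(a)+f(b)}{2}\, d(a,b),$$

with $d$ the center-to-center distance ($s$, $s\sqrt2$, or $s\sqrt5$).
The averaged-endpoint rule is the common cumulative-cost convention; the
literature the package follows names only "Dijkstra", so both the
connectivity and the edge-cost rule are declared package choices, not
inferences, and are exposed as configuration.

`accumulate_cost()` runs a single multi-source Dijkstra in C++ with a
deterministic heap order (ties break on lowest row, then column), so
outputs are bit-reproducible. `oracle_accumulate()` recomputes the same
contract by synchronous Bellman–Ford relaxation to fixpoint in plain R,
guarded to 64×64 grids; the two routes share nothing but the edge
definition, and the test suite requires exact (0 ULP) agreement on
random instances. That works because both accumulate path sums
left-to-right in the same operation order, and with positive weights
floating-point addition preserves the settle-order monotonicity Dijkstra
relies on.

Nodata friction cells are impassable. In memory, `NA` marks cells
outside the modelled domain and `Inf` marks passable cells with no path;
both collapse to the nodata sentinel on disk, and travel-time rasters
read back with nodata as `Inf`. Facilities landing on impassable cells
snap to the nearest passable cell within 5 cells (configurable);
facilities further than that are excluded and logged rather than
silently moved.

## Access metrics: numerical conventions

- **Thresholds are inclusive** (`tt <= 30` is "within 30 minutes"); the
  binary-raster formulation of coverage implies a single cutpoint, and
  the package fixes it on the inclusive side.
- **Weighted quantiles** use the left-continuous step inverse: the
  smallest value whose cumulative weight reaches $p\cdot W$. Many
  conventions exist; this one is stated because median/IQR values at
  coarse reporting precision can differ between them.
- **Default weighting is population**: quantiles and means weight cells
  with positive population by their population. Per-pixel weighting is
  available (`weighting = "pixel"`) because source descriptions of
  "per-pixel travel time summaries" are genuinely ambiguous; the choice
  is a visible argument, never hidden.
- **Unreachable cells** count as not covered at every threshold and sit
  in the upper quantile tail: quantiles stay finite as long as the
  unreachable weight fraction is below the quantile level, while means
  become `Inf` — a feature, since a finite mean over a partly
  unreachable stratum would be misleading.
- **Conservation by construction**: covered population plus red-zone
  (>60 min) population equals total population on every grid, because
  `NA` travel times count as uncovered rather than being dropped.
- **Rounding** is half-up to one decimal for reported minutes and
  percentages, matching how such tables are conventionally printed
  (base R rounds half-even). Unrounded values are always available from
  the underlying functions; only `build_report()` rounds.

## Facility registries

Service flags are tri-state (`yes`/`no`/`unknown`) and cost is
four-valued, because real directories have missing entries: summary
percentages can then be computed against all records or against records
with a known value, and published tables mix both conventions (e.g. a
morphine percentage over 504 known records out of 526). Both policies
are supported and the policy used is recorded in the output rather than
baked in.

Deduplication is a greedy first-wins pass in input order within a radius
(0 m within one source, 100 m across sources by default). The rule is an
artifact decision — source material states only that coordinate
duplicates were removed — so it is simple, order-stable, idempotent, and
fully logged. In scenario unions the tiers are concatenated in fixed
order (PCC, TH, DH, CHC, PHC), which makes directory centres win
coordinate ties over public facilities; precedence is unstated in the
source material, and this choice keeps directory provenance.

## The synthetic world

The generator emulates the statistical structure the analysis assumes,
not any real geography:

- **Friction**: off-road base 0.01 min/m (6 km/h), multiplicative
  smoothed lognormal roughness capped at 0.04 min/m (1.5 km/h), and road
  corridors at exactly 0.0012 min/m (50 km/h) connecting urban cluster
  sites. Values bracket the motorised range of global friction layers at
  1 km resolution.
- **Population**: 5 million people on a 96×96 km grid; 30% urban in
  Gaussian cluster kernels (a rural-majority country), the rest as iid
  lognormal rural background. The urban mask is kernel membership, so
  the rural/urban partition — and the 30% urban population share — are
  exact by construction.
- **Zones**: a 6-zone Voronoi partition; zone 1 is the "favored" zone
  holding 44.5% of directory (PCC) centres, emulating the one-state
  concentration of specialised centres that motivates zonal reporting.
- **Facilities**: tier counts 60/8/15/60/350 (PCC/TH/DH/CHC/PHC) with
  urban bias falling from 0.9 (TH) to 0.2 (PHC) — abundance rises and
  urban concentration falls down the tier ladder.

Everything is a pure function of an integer seed (each operation
re-seeds base R's RNG and restores the caller's stream), so worlds are
byte-identical across runs and platforms.

What a green test on this world establishes: the pipeline's arithmetic,
invariants (threshold and scenario monotonicity, conservation,
additivity), and qualitative reproductions (rural medians exceed urban
medians in every zone that has both strata; the favored zone has the
highest APC-30; the red-zone population falls as tiers are added, with
the public-only scenario nearly matching the full one). What it cannot
establish: agreement with any real country's published values, which
depend on external rasters and directories far beyond desk scale — those
quantities are covered only by the closed-form arithmetic that *is*
reproducible (density and service-percentage worked examples).

One stated-world caveat: in the default seed-42 world one zone contains
no urban cells, so its rural/urban comparison is undefined; the report
flags the stratum and comparisons are made over zones where both strata
exist.

## I/O

With no GIS stack assumed, the package carries a minimal GeoTIFF codec:
classic TIFF, single band, uncompressed strips, integer or IEEE-float
samples, either byte order on read, with `ModelPixelScale`/
`ModelTiepoint` georeferencing and the GDAL nodata tag. Float kinds are
stored as 64-bit, so write-then-read is the identity bit-for-bit;
categorical kinds (zone, mask, heatmap class) are stored as 32-bit
integers. The test suite cross-checks the codec in both directions
against an independent TIFF implementation. Compressed, tiled,
multi-band, or BigTIFF inputs are rejected with explicit messages —
convert such files with any GIS tool first.

## Known limitations

- No reprojection/resampling: inputs must already share one grid
  (`align_check()` is enforced everywhere).
- Grid-graph travel time underestimates network constraints (rivers
  without bridges, one-ways) and ignores congestion.
- Greedy dedup is order-dependent by design; a different input order can
  keep a different member of a duplicate cluster (never more than one).
- The synthetic road network is a set of straight corridors, not a
  topology; settlement placement is not gravity-modelled.
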