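---
title: "Range metrics and preliminary criterion-B assessment: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Range metrics and preliminary criterion-B assessment: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conrange)
```

## The problem

Red List assessment under criterion B asks how geographically restricted a
taxon is, using two complementary metrics computed from its known
occurrences:

* **Extent of occurrence (EOO)** — the area of the smallest convex polygon
  containing every occurrence site. It measures the overall spread of the
  range, including gaps.
* **Area of occupancy (AOO)** — the summed area of the cells of a regular
  grid that contain at least one occurrence, at a stated cell size. It
  measures how much of that spread is actually occupied.

`conrange` computes both from decimal latitude/longitude records, applies
the fixed criterion-B thresholds, and reports a *preliminary* category.
Preliminary is a substantive qualifier: a real criterion-B listing also
requires subcriteria (severe fragmentation or few locations, continuing
decline, extreme fluctuation) that no range geometry can establish, so the
package always attaches that caveat to its ratings.

## The pipeline

`run_analysis()` composes five deterministic steps:

1. **Validation** (`validate_occurrences()`): records with missing
   coordinates, impossible coordinates, or a suspected latitude/longitude
   swap (|lat| > 90 but ≤ 180) are hidden from analysis. Swaps are flagged,
   never auto-corrected — whether a pair is swapped or simply wrong needs a
   person who knows the taxon. Exact coordinate duplicates are reported but
   stay visible: repeat collections at a site are real data.
2. **Projection** (`project_points()`): see below.
3. **EOO** (`compute_eoo()`): quickhull convex hull plus shoelace area.
4. **Cell width** (`resolve_cell_width()`) and **AOO** (`compute_aoo()`).
5. **Rating** (`preliminary_rating()`).

Hidden records — whether hidden by the user, a filter, or validation — are
excluded from *every* metric, but are retained in `.geocat` files, CSV and
KML exports with their flag, so no edit loses data.

## The equal-area projection

EOO and AOO are areas in km², so the geometry must be done in a planar
frame that preserves area; degrees are not such a frame (a degree of
longitude shrinks with latitude). We use a Lambert cylindrical equal-area
projection of the authalic sphere (radius 6371.0072 km, the sphere with the
Earth's surface area), centred per dataset:

$$x = R\,(\lambda - \lambda_0)\cos\varphi_{ts}, \qquad
  y = R\,\frac{\sin\varphi}{\cos\varphi_{ts}}$$

with the central meridian $\lambda_0$ at the midpoint of the occupied
longitude arc and the standard parallel $\varphi_{ts}$ at the mean latitude
of the visible points. Equal-area is exact in this family for any
$\varphi_{ts}$; centring on the data minimises *shape* distortion where the
points are, which matters for the hull's appearance and for the AOO grid
being roughly square on the ground. The parameters used are stored in the
project file (`parameters.projection`) at full precision, because the AOO
grid is anchored at the projected origin: re-running with the same
parameters reproduces the same cells exactly.

Longitudes are treated as 360-periodic. A point set straddling the ±180°
seam is recentred (the occupied arc is found via the largest empty gap on
the longitude circle); a set spanning ≥ 180° of longitude is refused, since
a planar hull of such a set is not meaningful. Latitude of true scale is
clamped to ±89.9° to keep the projection non-degenerate for near-polar
datasets.

## EOO: strict quickhull and shoelace area

The hull is computed by the quickhull divide-and-conquer algorithm on the
deduplicated points. Output is canonical: the *strict* hull (collinear
boundary points are not vertices — the area is unaffected and the vertex
list is unique), ordered counter-clockwise starting from the lowest-x
(ties: lowest-y) vertex. In the recursion the farthest point from the
dividing chord is selected (first index on exact ties), so identical inputs
always give byte-identical output. The area is the shoelace formula
$\tfrac12\,|\sum_i (x_i y_{i+1} - x_{i+1} y_i)|$.

Fewer than three non-collinear points have no hull area: `compute_eoo()`
reports area 0 with `degenerate = TRUE` rather than pretending 0 km² is a
measurement. The rating step then rates from AOO alone (reporting the EOO
category as not applicable), unless `eoo_floor_aoo = TRUE` opts into the
convention that EOO is never smaller than AOO.

## AOO: grid occupancy

Each projected point is snapped to the lower-left corner of its cell,
$\lfloor c/w \rfloor \cdot w$ per coordinate. Cells are half-open
$[kw, (k+1)w)$, so a point exactly on a boundary belongs to the higher
cell, and negative coordinates use true floor, not truncation. Occupied
cells are deduplicated; per-cell point counts are kept as a
collection-density summary; AOO is $n_{cells} \cdot w^2$.

Three cell-width rules:

| rule | width | rationale |
|------|-------|-----------|
| `default` | 2 km | the IUCN-guideline reference grid (cell area 4 km²) |
| `user` | any $w > 0$ km | taxon- or data-specific scales |
| `tenth_max_dist` | diameter / 10 | grid scales with the range; the factor 10 mirrors the ratio between the EOO and AOO thresholds in criterion B |

A note on "2 km": grid sizes for AOO are quoted ambiguously in the
literature as "2 km cells" or "2 km² cells". We interpret the reference
grid as cell *width* 2 km (area 4 km²), the grid the IUCN guidelines
actually prescribe; the constant is a single definition
(`DEFAULT_CELL_WIDTH_KM`) should a different convention ever be needed.
When all points coincide the auto rule's diameter is zero; it falls back to
the 2 km default with a warning rather than producing a zero-width grid.

Because the grid is anchored at the projected origin and the projection is
data-centred, AOO depends (as any gridded AOO does) on grid placement;
serializing the projection parameters makes every reported AOO exactly
reproducible.

## Rating

Criterion-B thresholds (IUCN Categories and Criteria v3.1; configuration
constants, not outputs of this package):

| category | EOO (B1) | AOO (B2) |
|----------|----------|----------|
| CR | < 100 km² | < 10 km² |
| EN | < 5,000 km² | < 500 km² |
| VU | < 20,000 km² | < 2,000 km² |

Comparison is strict less-than: an area exactly on a threshold takes the
less threatened category. Above VU the package reports the combined label
`LC_or_NT` — separating Least Concern from Near Threatened requires
information beyond range size. The consolidated preliminary rating is the
more threatened of the two per-metric categories, since either subcriterion
can qualify a taxon.

## File formats

* **CSV**: generic (`latitude`/`longitude`) and GBIF-download
  (`decimalLatitude`/`decimalLongitude`, delimiter auto-detected) dialects,
  case-insensitive headers. Unparseable coordinate rows are skipped and
  counted. Per-source display caps (500 for GBIF, 250 for Flickr,
  unlimited otherwise) hide — never drop — rows beyond the cap, in file
  order, with a warning.
* **`.geocat` JSON**: occurrences, parameters, results and opaque
  application state in one versioned document. Degrees are serialized at 6
  decimal places (≈ 0.1 m), areas at 4; writers use a fixed key order, so
  identical projects give byte-identical files and unknown top-level keys
  survive a round trip.
* **KML 2.2**: one Placemark per occurrence (hidden records get a distinct
  style, so the export documents the whole dataset), the hull and each AOO
  cell as Polygons, coordinates in lon,lat order with closed rings.

## The synthetic generator

`generate_fixture()` produces seeded occurrence sets: uniform scatter or
three Gaussian clusters (sd 5 % of the extent span) — the clumped
collecting localities typical of herbarium data — over a default 2° × 2°
equatorial box at longitudes above 90°, so that an injected lat/lon swap
yields an impossible latitude and is detectable the same way real swaps
are. Defect injection (swapped, missing, duplicated coordinates at stated
rates) exercises the validator. Coordinates are rounded to 6 decimal
places, typical GPS precision, which also makes file round trips exact.

What the generator does *not* emulate: spatial autocorrelation of real
collecting effort, coastline/political clipping, datum errors other than
swaps, and textual metadata noise. Tests passing on these fixtures
demonstrate the geometry, bookkeeping and formats are correct; they do not
validate any ecological interpretation of a particular dataset.

## Numerical choices and problem sizes

* Hull orientation tests tolerate 1e-9 km in the point-in-hull signed-area
  check; cross products are otherwise compared exactly (duplicates are
  removed first, and ties take the first index).
* Projection round trips are verified to 1e-9°, the equal-area property to
  1e-6 relative error against the closed-form spherical zone area, on 1,000
  random points.
* Algorithm equivalence is checked against independently implemented
  oracles: gift-wrapping (hull), fan triangulation (area),
  rectangle-containment (grid occupancy), a double loop (diameter) — 1,000
  random point sets (n ≤ 50) for the hull and 500 for occupancy, sizes at
  which the oracles are fast and every disagreement would be visible.
* `validate_occurrences()` assigns one primary reason per record
  (missing > swap > out-of-range); duplicate pairs are counted as
  $\binom{k}{2}$ per coincident group.

## Limitations

* The rating is preliminary by construction; subcriteria are out of scope.
* Areas are spherical (authalic), not ellipsoidal; the difference is well
  below the thresholds' granularity for assessment purposes.
* α-hulls, temporal (criterion A) analysis, and live queries to occurrence
  aggregators are not provided; data enters via CSV or `.geocat` files.
* AOO at non-default widths is not rescaled to the 2 km reference scale;
  comparing AOO values across widths is the user's responsibility.
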