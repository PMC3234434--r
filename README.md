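# conrange

Geospatial range metrics for preliminary IUCN Red List criterion-B
assessment, computed offline from georeferenced species occurrence
records.

Criterion B of the Red List rates taxa by geographic restriction using two
metrics: **extent of occurrence** (EOO), the area of the convex hull of
all occurrence sites, and **area of occupancy** (AOO), the summed area of
occupied grid cells at a stated cell width. Both have historically been
computed inconsistently across assessments; `conrange` makes them
repeatable: records in, cleaned and filtered with an audit trail, areas in
true km², thresholds applied, a preliminary category out — plus project
files so an assessment can be saved, shared and re-run byte-identically.

It is intended for conservation scientists and biodiversity informaticians
preparing criterion-B evidence, and works equally as a georeference
screening tool (swapped lat/lon pairs, impossible coordinates, duplicates).

## The method in brief

Visible records are projected into a per-dataset Lambert cylindrical
equal-area frame on the authalic sphere (R = 6371.0072 km):

    x = R (λ − λ0) cos φts,   y = R sin φ / cos φts

with λ0 and φts centred on the data, so planar areas equal spherical
areas. Then:

* **EOO** = shoelace area of the strict convex hull (quickhull algorithm),
  in km²; fewer than 3 non-collinear points are reported as degenerate,
  not as 0 km² of range.
* **AOO** = n_cells × w², where each point is snapped to its cell's
  lower-left corner by `floor(coord / w) * w`. Cell width `w` is 2 km by
  default (the IUCN reference grid), user-set, or 1/10 of the maximum
  pairwise distance.
* **Rating**: strict `<` lookup against the criterion-B thresholds
  (EOO: CR < 100, EN < 5,000, VU < 20,000 km²; AOO: CR < 10, EN < 500,
  VU < 2,000 km²); the preliminary category is the more threatened of the
  two, always with the caveat that full listings require subcriteria this
  package does not assess.

Details, conventions and design rationale are in the methods vignette,
`vignettes/range-assessment.Rmd`.

## Worked example

```r
library(conrange)

# a seeded synthetic dataset: 60 records in 3 Gaussian clusters
occ <- generate_fixture(n = 60, pattern = "gaussian_clusters", seed = 5)

project <- run_analysis(geocat_project(occ))
generate_report(project)
```

```
Preliminary criterion-B assessment: Synthetic taxon
Occurrences: 60 total, 60 visible in analysis, 0 edited
EOO: 14703.7476 km2 -> VU
AOO: 236.0000 km2 (59 cell(s) at 2.0000 km width) -> EN
Preliminary rating: EN
Cell-width rule: default
Projection: cylindrical equal-area lon0=110.875178 lat_ts=0.189972 R=6371.0072 km
Preliminary rating from range metrics only, subject to meeting the full requirements of the criteria (criterion-B subcriteria on fragmentation, locations, decline and fluctuation are not assessed).
```

Reading: the hull of the 60 points encloses 14,703.75 km² (between 5,000
and 20,000, hence VU under B1); the points occupy 59 of the 2-km grid
cells, 236 km² (between 10 and 500, hence EN under B2); the consolidated
preliminary rating is the more threatened of the two, EN. The results can
then be persisted and exported:

```r
write_geocat(project, "taxon.geocat")   # JSON project file, reloadable with read_geocat()
export_kml(project, "taxon.kml")        # points + hull + cells for Google Earth
write_occurrence_csv(project$occurrence_set, "taxon.csv")
```

Real data enters through `read_occurrence_csv()` (generic
`latitude`/`longitude` or GBIF-download `decimalLatitude`/
`decimalLongitude` dialects), is cleaned with `validate_occurrences()`,
`filter_bbox()`, `filter_precision()` and `edit_point()`, and multi-species
files are assessed in one call with `run_batch()`.

A thin command-line wrapper around the same functions is available at
`exec/geocat`:

```sh
exec/geocat analyze occurrences.csv --dialect gbif --out taxon.geocat --kml taxon.kml
exec/geocat batch multispecies.csv --taxon-column taxon
exec/geocat fixture --n 100 --seed 42 --out fixture.csv
```

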