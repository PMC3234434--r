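Package: conrange
Title: Geospatial Range Metrics and Preliminary IUCN Criterion B Assessment
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computes the two range-size metrics underpinning criterion B of
    the IUCN Red List from georeferenced species occurrence records: extent of
    occurrence (EOO) as the area of the convex hull of the occurrences, and
    area of occupancy (AOO) as the summed area of occupied grid cells.
    Occurrences are cleaned and filtered (coordinate validation, bounding-box
    and coordinate-precision filters, point editing with an audit trail),
    projected into a per-dataset cylindrical equal-area frame so areas are in
    true square kilometres, and mapped to a preliminary criterion-B threat
    category. Supports generic and GBIF-download CSV input, JSON project files
    that round-trip data, parameters, results and application state, KML
    export, batch assessment of multi-species files, and a seeded synthetic
    occurrence generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
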