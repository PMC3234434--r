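# Hand-computable end-to-end fixture: four points whose equal-area
# projection is a 4 km square centred on the origin. With lats at
# +/- asin(2/R) and lons at 0 and (4/R) rad, the data-derived frame has
# lat_ts = 0 and lon0 at the mid-longitude, so the corners land at
# (+/-2, +/-2) km: EOO = 16 km^2, AOO at 2 km width = 4 corner cells
# = 16 km^2, preliminary rating CR (EOO 16 < 100).
make_square_set <- function() {
  R <- 6371.0072
  a <- asin(2 / R) * 180 / pi
  b <- (4 / R) * 180 / pi
  occurrence_set("Square test taxon",
                 lat = c(-a, -a, a, a),
                 lon = c(0, b, 0, b))
}

# small mixed-quality set used by the editing/validation tests
make_messy_set <- function() {
  occurrence_set(
    "Messy taxon",
    lat = c(10, 120, NA, 10, 10, 95, 200),
    lon = c(20, 30, 40, 20, 21, 50, 60),
    id = c("ok1", "swap", "miss", "dupA", "dupB", "swap2", "range"),
    uncertainty_m = c(100, NA, NA, 5000, NA, NA, NA)
  )
}
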