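test_that("validation flags swaps, missing and out-of-range coords and hides them", {
  vr <- validate_occurrences(make_messy_set())
  expect_s3_class(vr, "validation_report")
  expect_equal(unname(vr$counts["missing"]), 1)
  expect_equal(unname(vr$counts["suspected_swap"]), 2)   # lat 120 and 95
  expect_equal(unname(vr$counts["out_of_range"]), 1)     # lat 200
  expect_equal(unname(vr$counts["duplicate_pairs"]), 1)  # dupA/dupB

  r <- vr$set$records
  expect_false(any(r$visible[r$id %in% c("swap", "swap2", "miss", "range")]))
  # duplicates stay visible; the coordinates are not auto-corrected
  expect_true(all(r$visible[r$id %in% c("dupA", "dupB", "ok1")]))
  expect_equal(r$lat[r$id == "swap"], 120)
  expect_setequal(vr$flags$reason[vr$flags$id == "swap"], "possible_latlon_swap")
})

test_that("an all-valid set validates with zero counts", {
  set <- occurrence_set("clean", lat = seq(0, 9), lon = seq(10, 19))
  vr <- validate_occurrences(set)
  expect_true(all(vr$counts == 0))
  expect_equal(nrow(vr$flags), 0)
  expect_true(all(vr$set$records$visible))
})

test_that("validation refuses an empty set", {
  set <- occurrence_set("empty", lat = numeric(0), lon = numeric(0))
  expect_error(validate_occurrences(set), "no occurrences")
})

test_that("three identical coordinates count as three duplicate pairs", {
  set <- occurrence_set("trip", lat = c(1, 1, 1), lon = c(2, 2, 2))
  expect_equal(unname(validate_occurrences(set)$counts["duplicate_pairs"]), 3)
})

test_that("bbox filtering is boundary-inclusive and respects its mode", {
  set <- occurrence_set("bb", lat = c(0, 10, 5), lon = c(0, 0, 0),
                        id = c("lo", "hi", "edge"))
  bb <- c(min_lat = 5, min_lon = -180, max_lat = 15, max_lon = 180)

  hid <- filter_bbox(set, bb, "hide_inside")
  expect_equal(hid$records$visible, c(TRUE, FALSE, FALSE))  # edge point is inside

  out <- filter_bbox(set, bb, "hide_outside")
  expect_equal(out$records$visible, c(FALSE, TRUE, TRUE))

  del <- filter_bbox(set, bb, "delete_inside")
  expect_equal(del$records$id, "lo")

  # the two hide modes partition the set: every point hidden by exactly one
  both <- filter_bbox(hid, bb, "hide_outside")
  expect_false(any(both$records$visible))

  world <- c(min_lat = -90, min_lon = -180, max_lat = 90, max_lon = 180)
  expect_equal(filter_bbox(set, world, "hide_outside")$records$visible,
               set$records$visible)
})

test_that("inverted bounding boxes are rejected", {
  set <- occurrence_set("bb", lat = 0, lon = 0)
  expect_error(
    filter_bbox(set, c(min_lat = 10, min_lon = 0, max_lat = 0, max_lon = 1)),
    "inverted"
  )
})

test_that("precision filter hides only records above the threshold", {
  set <- occurrence_set("prec", lat = c(1, 2, 3), lon = c(1, 2, 3),
                        uncertainty_m = c(100, 5000, NA))
  f <- filter_precision(set, 1000)
  expect_equal(f$records$visible, c(TRUE, FALSE, TRUE))
  expect_equal(filter_precision(set, 1e9)$records$visible, rep(TRUE, 3))
  expect_error(filter_precision(set, 0), "positive")

  none <- occurrence_set("prec", lat = 1, lon = 1)
  expect_warning(filter_precision(none, 1000), "no-op")
})

test_that("filters never change coordinates", {
  set <- make_messy_set()
  bb <- c(min_lat = 0, min_lon = 0, max_lat = 50, max_lon = 50)
  f <- filter_precision(filter_bbox(set, bb, "hide_inside"), 1000)
  expect_identical(f$records$lat, set$records$lat)
  expect_identical(f$records$lon, set$records$lon)
  expect_false(any(f$records$edited))
})

test_that("point edits move/hide/show/delete and append to the audit trail", {
  set <- occurrence_set("ed", lat = c(1, 2), lon = c(3, 4), id = c("a", "b"))

  m <- edit_point(set, "a", "move", new_coords = c(1.5, 2.5))
  expect_equal(m$records$lat[1], 1.5)
  expect_equal(m$records$lon[1], 2.5)
  expect_true(m$records$edited[1])

  hs <- edit_point(edit_point(set, "a", "hide"), "a", "show")
  expect_true(hs$records$visible[1])
  expect_identical(hs$records, set$records)  # involution up to the audit trail
  expect_length(hs$provenance$audit, 2)

  d <- edit_point(set, "b", "delete")
  expect_equal(d$records$id, "a")

  expect_error(edit_point(set, "zzz", "delete"), "unknown id")
  expect_error(edit_point(set, "a", "move"), "new_coords")
  expect_error(edit_point(set, "a", "move", new_coords = c(91, 0)), "invalid")
})

test_that("audit trail length equals the number of edits applied", {
  set <- occurrence_set("ed", lat = c(1, 2, 3), lon = c(1, 2, 3),
                        id = c("a", "b", "c"))
  set <- edit_point(set, "a", "hide")
  set <- edit_point(set, "b", "move", new_coords = c(5, 5))
  set <- edit_point(set, "c", "delete")
  expect_length(set$provenance$audit, 3)
})
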