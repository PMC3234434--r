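test_that("the square fixture runs end to end with hand-computable results", {
  project <- run_analysis(geocat_project(make_square_set()))
  res <- project$results
  expect_equal(res$eoo$area_km2, 16, tolerance = 1e-6)
  expect_equal(res$aoo$cell_width_km, 2)
  expect_equal(res$aoo$n_cells, 4)
  expect_equal(res$aoo$area_km2, 16)
  expect_equal(res$rating$eoo_category, "CR")
  expect_equal(res$rating$aoo_category, "EN")
  expect_equal(res$rating$preliminary, "CR")
  expect_equal(project$parameters$cell_width_km, res$aoo$cell_width_km)
})

test_that("hidden and invalid points are excluded from every metric", {
  set <- make_square_set()
  # one extra far-away point, hidden: results must match the plain square
  lat <- c(set$records$lat, 5); lon <- c(set$records$lon, 5)
  bigger <- occurrence_set(set$taxon, lat = lat, lon = lon,
                           visible = c(rep(TRUE, 4), FALSE))
  res <- run_analysis(geocat_project(bigger))$results
  expect_equal(res$eoo$area_km2, 16, tolerance = 1e-6)
  expect_equal(res$eoo$n_points_used, 4)
  expect_equal(res$aoo$n_cells, 4)
  expect_equal(sum(vapply(res$aoo$cells, `[[`, integer(1), "count")), 4)

  # an invalid coordinate is auto-hidden by validation, same result
  withbad <- occurrence_set(set$taxon, lat = c(set$records$lat, 120),
                            lon = c(set$records$lon, 5))
  res2 <- run_analysis(geocat_project(withbad))$results
  expect_equal(res2$eoo$n_points_used, 4)
  expect_equal(res2$aoo$n_cells, 4)
})

test_that("analysing a project with no usable points is an error", {
  hidden <- occurrence_set("x", lat = c(1, 2), lon = c(1, 2),
                           visible = FALSE)
  expect_error(run_analysis(geocat_project(hidden)), "no visible")
})

test_that("the report echoes the stored results exactly", {
  project <- run_analysis(geocat_project(make_square_set()))
  rep <- generate_report(project)
  expect_equal(rep$summary$eoo$area_km2, project$results$eoo$area_km2)
  expect_equal(rep$summary$aoo$n_cells, project$results$aoo$n_cells)
  expect_equal(rep$summary$preliminary, project$results$rating$preliminary)
  expect_equal(rep$summary$parameters$cell_width_km,
               project$parameters$cell_width_km)
  expect_match(paste(rep$lines, collapse = "\n"), "Preliminary rating: CR")
  expect_true(any(grepl(sprintf("EOO: %.4f", project$results$eoo$area_km2),
                        rep$lines, fixed = TRUE)))

  tp <- withr::local_tempfile(fileext = ".txt")
  jp <- withr::local_tempfile(fileext = ".json")
  generate_report(project, text_path = tp, json_path = jp)
  expect_identical(readLines(tp), rep$lines)
  twin <- jsonlite::fromJSON(jp)
  expect_equal(twin$eoo$area_km2, project$results$eoo$area_km2)

  expect_error(generate_report(geocat_project(make_square_set())), "no results")
})

test_that("batch assessment matches per-species single runs", {
  sq <- make_square_set()
  other <- generate_fixture(20, "gaussian_clusters", seed = 13,
                            taxon = "Other taxon")
  path <- withr::local_tempfile(fileext = ".csv")
  lines <- c("taxon,latitude,longitude",
             sprintf("Square,%0.10f,%0.10f", sq$records$lat, sq$records$lon),
             sprintf("Other,%0.6f,%0.6f", other$records$lat,
                     other$records$lon),
             "Broken,999,999")
  writeLines(lines, path)

  tab <- run_batch(path)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$status[tab$taxon == "Broken"], "failed")
  expect_equal(tab$status[tab$taxon != "Broken"], rep("ok", 2))
  sq_row <- tab[tab$taxon == "Square", ]
  expect_equal(sq_row$eoo_km2, 16, tolerance = 1e-4)
  expect_equal(sq_row$aoo_km2, 16)
  expect_equal(sq_row$preliminary, "CR")

  single <- run_analysis(geocat_project(other))$results
  oth_row <- tab[tab$taxon == "Other", ]
  expect_equal(oth_row$eoo_km2, single$eoo$area_km2)
  expect_equal(oth_row$aoo_km2, single$aoo$area_km2)
  expect_equal(oth_row$n_cells, single$aoo$n_cells)

  expect_error(run_batch(path, taxon_column = "species"), "not found")
})

test_that("the fixture generator is seed-reproducible with controlled defects", {
  a <- generate_fixture(100, "gaussian_clusters", seed = 21,
                        swap_rate = 0.05, missing_rate = 0.05,
                        duplicate_rate = 0.05)
  b <- generate_fixture(100, "gaussian_clusters", seed = 21,
                        swap_rate = 0.05, missing_rate = 0.05,
                        duplicate_rate = 0.05)
  expect_identical(a$records, b$records)
  expect_equal(nrow(a$records), 100)
  expect_length(a$provenance$swapped_ids, 5)
  expect_length(a$provenance$missing_ids, 5)
  expect_length(a$provenance$duplicate_ids, 5)

  vr <- validate_occurrences(a)
  expect_equal(unname(vr$counts["missing"]), 5)
  expect_equal(unname(vr$counts["suspected_swap"]), 5)
  expect_gte(unname(vr$counts["duplicate_pairs"]), 5)

  c_ <- generate_fixture(100, "gaussian_clusters", seed = 22)
  expect_false(identical(a$records$lat, c_$records$lat))
  expect_error(generate_fixture(0), ">= 1")

  # generator restores the caller's RNG state
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(generate_fixture(10, seed = 4))
  expect_identical(runif(1), before)
})

test_that("re-running the pipeline on identical input is byte-deterministic", {
  paths <- c(withr::local_tempfile(fileext = ".geocat"),
             withr::local_tempfile(fileext = ".geocat"))
  for (k in 1:2) {
    pr <- run_analysis(geocat_project(
      generate_fixture(40, "gaussian_clusters", seed = 31)))
    write_geocat(pr, paths[k])
  }
  expect_identical(readLines(paths[1]), readLines(paths[2]))
})
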