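# One-shot assessment pipeline: validate -> project -> EOO -> cell width ->
# AOO -> preliminary rating. The pipeline is purely deterministic for a
# given input, so re-running a saved project reproduces its results
# byte-for-byte.

#' Analysis parameters
#'
#' @param cell_width_rule A [cell_width_rule()]; default is the 2 km IUCN
#'   guideline grid.
#' @param eoo_floor_aoo Passed to [preliminary_rating()]: when the EOO hull
#'   is degenerate, rate the AOO area under criterion B1 as well.
#' @param caps Per-source display caps (see [default_source_caps()]);
#'   recorded with the project so imports are reproducible.
#' @param seed Optional integer, recorded when the occurrences came from
#'   [generate_fixture()].
#' @return An object of class `analysis_params`. After [run_analysis()] it
#'   additionally carries `cell_width_km` (the resolved width actually used)
#'   and `projection` (the equal-area frame the results are expressed in).
#' @export
analysis_params <- function(cell_width_rule = conrange::cell_width_rule("default"),
                            eoo_floor_aoo = FALSE,
                            caps = default_source_caps(),
                            seed = NULL) {
  stopifnot(inherits(cell_width_rule, "cell_width_rule"))
  structure(list(
    cell_width_rule = cell_width_rule,
    cell_width_km = NULL,
    eoo_floor_aoo = isTRUE(eoo_floor_aoo),
    caps = caps,
    seed = seed,
    projection = NULL
  ), class = "analysis_params")
}

#' Run the full assessment pipeline on a project
#'
#' Validates the occurrences (hiding records with missing or impossible
#' coordinates), projects the visible records into the data-centred
#' equal-area frame, computes EOO and AOO, and derives the preliminary
#' criterion-B rating. Results, the resolved cell width and the projection
#' parameters are stored back into the project, ready for
#' [write_geocat()], [export_kml()] or [generate_report()].
#'
#' The projection is always derived from the current visible points, so
#' editing a project and re-running updates the frame consistently; the
#' frame used is recorded in `parameters$projection`.
#'
#' @param project A [geocat_project()] with at least one visible valid
#'   occurrence.
#' @param params An [analysis_params()]; defaults to the project's own.
#' @return The project with `$results` filled in: `eoo` (`area_km2`,
#'   `n_points_used`, `degenerate`, `hull_lonlat`), `aoo` (`cell_width_km`,
#'   `n_cells`, `area_km2`, `cells` as `i`/`j`/`count` triples) and `rating`.
#'   Areas are recorded at 4 decimal places, degrees at 6.
#' @export
run_analysis <- function(project, params = project$parameters) {
  stopifnot(inherits(project, "geocat_project"),
            inherits(params, "analysis_params"))
  vr <- validate_occurrences(project$occurrence_set)
  set <- vr$set
  set$provenance$validation <- vr$counts

  projected <- project_points(set)
  eoo <- compute_eoo(projected)
  width <- resolve_cell_width(params$cell_width_rule,
                              projected$points[, c("x", "y")])
  aoo <- compute_aoo(projected, width)
  rating <- preliminary_rating(eoo, aoo, params$eoo_floor_aoo)

  hull_ll <- project_inverse(eoo$hull[, 1], eoo$hull[, 2], projected$params)
  params$cell_width_km <- round6(width)
  params$projection <- projected$params

  project$occurrence_set <- set
  project$parameters <- params
  project$results <- list(
    eoo = list(
      area_km2 = round4(eoo$area_km2),
      n_points_used = eoo$n_points_used,
      degenerate = eoo$degenerate,
      hull_lonlat = unname(lapply(seq_len(nrow(hull_ll)), function(i) {
        list(round6(hull_ll$lon[i]), round6(hull_ll$lat[i]))
      }))
    ),
    aoo = list(
      cell_width_km = round6(width),
      n_cells = aoo$n_cells,
      area_km2 = round4(aoo$area_km2),
      cells = unname(lapply(seq_len(nrow(aoo$cells)), function(k) {
        list(i = as.integer(aoo$cells$i[k]), j = as.integer(aoo$cells$j[k]),
             count = aoo$cells$count[k])
      }))
    ),
    rating = list(
      eoo_category = rating$eoo_category,
      aoo_category = rating$aoo_category,
      preliminary = rating$preliminary,
      caveat_note = rating$caveat_note
    )
  )
  project
}

#' Render the assessment report
#'
#' A compact summary of an analysed project: record counts, the two range
#' metrics with their per-criterion categories, and the consolidated
#' preliminary rating with its caveat. Every number in the report is taken
#' verbatim from `project$results`.
#'
#' @param project An analysed [geocat_project()] (results present).
#' @param text_path,json_path Optional output paths for the plain-text
#'   report and its machine-readable JSON twin.
#' @return An object of class `report_summary`: list with `lines` (the text
#'   report) and `summary` (the JSON twin as a list), invisibly when writing
#'   to file.
#' @export
generate_report <- function(project, text_path = NULL, json_path = NULL) {
  stopifnot(inherits(project, "geocat_project"))
  res <- project$results
  if (is.null(res)) stop("no results: run run_analysis() first")
  r <- project$occurrence_set$records
  p <- project$parameters
  summary <- list(
    taxon = project$taxon_name,
    n_total = nrow(r),
    n_visible = sum(r$visible),
    n_edited = sum(r$edited),
    eoo = res$eoo[c("area_km2", "degenerate", "n_points_used")],
    eoo_category = res$rating$eoo_category,
    aoo = res$aoo[c("cell_width_km", "n_cells", "area_km2")],
    aoo_category = res$rating$aoo_category,
    preliminary = res$rating$preliminary,
    caveat = res$rating$caveat_note,
    parameters = params_to_plain(p)
  )
  lines <- c(
    sprintf("Preliminary criterion-B assessment: %s", summary$taxon),
    sprintf("Occurrences: %d total, %d visible in analysis, %d edited",
            summary$n_total, summary$n_visible, summary$n_edited),
    sprintf("EOO: %.4f km2%s -> %s", res$eoo$area_km2,
            if (res$eoo$degenerate) " (degenerate, <3 non-collinear points)" else "",
            res$rating$eoo_category),
    sprintf("AOO: %.4f km2 (%d cell(s) at %.4f km width) -> %s",
            res$aoo$area_km2, res$aoo$n_cells, res$aoo$cell_width_km,
            res$rating$aoo_category),
    sprintf("Preliminary rating: %s", res$rating$preliminary),
    sprintf("Cell-width rule: %s", p$cell_width_rule$kind),
    sprintf("Projection: cylindrical equal-area lon0=%.6f lat_ts=%.6f R=%.4f km",
            p$projection$lon0, p$projection$lat_ts, p$projection$R),
    res$rating$caveat_note
  )
  out <- structure(list(lines = lines, summary = summary),
                   class = "report_summary")
  if (!is.null(text_path)) {
    con <- file(text_path, open = "wb")
    writeLines(lines, con, sep = "\n")
    close(con)
  }
  if (!is.null(json_path)) {
    con <- file(json_path, open = "wb")
    writeLines(jsonlite::toJSON(summary, auto_unbox = TRUE, digits = NA,
                                null = "null", pretty = 2), con, sep = "\n")
    close(con)
  }
  if (is.null(text_path) && is.null(json_path)) out else invisible(out)
}

#' @export
print.report_summary <- function(x, ...) {
  cat(x$lines, sep = "\n")
  invisible(x)
}

#' Batch assessment of a multi-species occurrence file
#'
#' Splits one CSV by its taxon column and runs the full pipeline on each
#' species independently (each gets its own data-centred projection). A
#' species whose records cannot be analysed (e.g. no valid coordinates)
#' yields a `"failed"` row with the error message rather than aborting the
#' batch.
#'
#' @param path Occurrence CSV containing a taxon column.
#' @param taxon_column Name of the taxon column (case-insensitive).
#' @param dialect,caps Passed to [read_occurrence_csv()].
#' @param params An [analysis_params()] applied to every species.
#' @return Data frame with one row per species: `taxon`, `status`
#'   (`"ok"`/`"failed"`), `n_records`, `n_visible`, `eoo_km2`,
#'   `eoo_category`, `cell_width_km`, `n_cells`, `aoo_km2`, `aoo_category`,
#'   `preliminary`, `message`.
#' @export
run_batch <- function(path, taxon_column = "taxon",
                      dialect = c("generic", "gbif"),
                      caps = default_source_caps(),
                      params = analysis_params()) {
  dialect <- match.arg(dialect)
  set <- read_occurrence_csv(path, dialect = dialect, caps = caps,
                             taxon = "batch")
  taxa <- vapply(set$records$metadata, function(m) {
    hit <- which(tolower(names(m)) == tolower(taxon_column))
    if (length(hit)) m[[hit[1]]] else NA_character_
  }, character(1))
  if (all(is.na(taxa))) {
    stop("taxon column '", taxon_column, "' not found in ", path)
  }
  taxa[is.na(taxa)] <- "(unknown)"

  rows <- lapply(unique(taxa), function(tx) {
    sub <- set
    sub$taxon <- tx
    sub$records <- set$records[taxa == tx, , drop = FALSE]
    rownames(sub$records) <- NULL
    n <- nrow(sub$records)
    ok <- try(run_analysis(geocat_project(sub, parameters = params)),
              silent = TRUE)
    if (inherits(ok, "try-error")) {
      data.frame(taxon = tx, status = "failed", n_records = n,
                 n_visible = NA_integer_, eoo_km2 = NA_real_,
                 eoo_category = NA_character_, cell_width_km = NA_real_,
                 n_cells = NA_integer_, aoo_km2 = NA_real_,
                 aoo_category = NA_character_, preliminary = NA_character_,
                 message = trimws(attr(ok, "condition")$message),
                 stringsAsFactors = FALSE)
    } else {
      res <- ok$results
      data.frame(taxon = tx, status = "ok", n_records = n,
                 n_visible = sum(ok$occurrence_set$records$visible),
                 eoo_km2 = res$eoo$area_km2,
                 eoo_category = res$rating$eoo_category,
                 cell_width_km = res$aoo$cell_width_km,
                 n_cells = res$aoo$n_cells,
                 aoo_km2 = res$aoo$area_km2,
                 aoo_category = res$rating$aoo_category,
                 preliminary = res$rating$preliminary,
                 message = "", stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
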