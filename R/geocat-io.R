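# `.geocat` project files: a single JSON document bundling the occurrence
# data, the analysis parameters, the results and opaque application state,
# so an assessment can be reloaded or passed to a collaborator and re-run
# exactly. Writers are deterministic: fixed key order, degrees at 6 decimal
# places, areas at 4, projection parameters at full precision (they anchor
# the AOO grid, so they must survive the round trip exactly). Unknown
# top-level keys in a file are preserved verbatim for forward compatibility.

GEOCAT_FORMAT_VERSION <- "1.0"

#' Assemble a project
#'
#' @param occurrence_set An [occurrence_set()].
#' @param parameters An [analysis_params()].
#' @param results Optional plain results list as produced by
#'   [run_analysis()].
#' @param app_state Named list of opaque application state (map centre,
#'   zoom, ...) passed through untouched.
#' @param taxon_name Defaults to the set's taxon.
#' @param extra Named list of unknown top-level keys carried over from a
#'   file written by a newer format version.
#' @return An object of class `geocat_project`.
#' @export
geocat_project <- function(occurrence_set, parameters = analysis_params(),
                           results = NULL, app_state = list(),
                           taxon_name = occurrence_set$taxon, extra = list()) {
  stopifnot(inherits(occurrence_set, "occurrence_set"))
  structure(list(
    format_version = GEOCAT_FORMAT_VERSION,
    taxon_name = taxon_name,
    occurrence_set = occurrence_set,
    parameters = parameters,
    results = results,
    app_state = app_state,
    extra = extra
  ), class = "geocat_project")
}

#' @export
print.geocat_project <- function(x, ...) {
  cat(sprintf("<geocat_project> %s: %d occurrence(s)%s\n", x$taxon_name,
              nrow(x$occurrence_set$records),
              if (is.null(x$results)) "" else "; results present"))
  invisible(x)
}

round6 <- function(x) as.numeric(sprintf("%.6f", x))
round4 <- function(x) as.numeric(sprintf("%.4f", x))

params_to_plain <- function(p) {
  out <- list(
    cell_width_rule = p$cell_width_rule$kind,
    cell_width_km = if (is.null(p$cell_width_km)) NULL else round6(p$cell_width_km),
    user_width_km = p$cell_width_rule$user_width_km,
    eoo_floor_aoo = p$eoo_floor_aoo,
    caps = as.list(p$caps)
  )
  if (!is.null(p$projection)) {
    out$projection <- list(lon0 = p$projection$lon0,
                           lat_ts = p$projection$lat_ts,
                           R = p$projection$R)
  }
  out
}

plain_to_params <- function(x) {
  rule <- cell_width_rule(x$cell_width_rule,
                          user_width_km = x$user_width_km)
  p <- analysis_params(
    cell_width_rule = rule,
    eoo_floor_aoo = isTRUE(x$eoo_floor_aoo),
    caps = if (length(x$caps)) unlist(x$caps) else default_source_caps()
  )
  p$cell_width_km <- x$cell_width_km
  if (!is.null(x$projection)) {
    p$projection <- projection_params(x$projection$lon0, x$projection$lat_ts,
                                      x$projection$R)
  }
  p
}

occ_to_plain <- function(set) {
  r <- set$records
  lapply(seq_len(nrow(r)), function(i) {
    list(
      id = r$id[i],
      lat = if (is.na(r$lat[i])) NULL else round6(r$lat[i]),
      lon = if (is.na(r$lon[i])) NULL else round6(r$lon[i]),
      source = r$source[i],
      visible = r$visible[i],
      edited = r$edited[i],
      uncertainty_m = if (is.na(r$uncertainty_m[i])) NULL else r$uncertainty_m[i],
      metadata = as.list(r$metadata[[i]])
    )
  })
}

plain_to_occ <- function(occ, taxon, provenance) {
  pick <- function(o, k, default) if (is.null(o[[k]])) default else o[[k]]
  occurrence_set(
    taxon = taxon,
    lat = vapply(occ, pick, numeric(1), k = "lat", default = NA_real_),
    lon = vapply(occ, pick, numeric(1), k = "lon", default = NA_real_),
    id = vapply(occ, `[[`, character(1), "id"),
    source = vapply(occ, pick, character(1), k = "source", default = "user"),
    visible = vapply(occ, pick, logical(1), k = "visible", default = TRUE),
    edited = vapply(occ, pick, logical(1), k = "edited", default = FALSE),
    uncertainty_m = vapply(occ, pick, numeric(1), k = "uncertainty_m",
                           default = NA_real_),
    metadata = lapply(occ, function(o) {
      m <- o$metadata
      if (is.null(m) || !length(m)) return(character(0))
      vapply(m, as.character, character(1))
    }),
    provenance = provenance
  )
}

#' Write a project to a `.geocat` file
#'
#' @param project A [geocat_project()].
#' @param path Output path (conventionally `*.geocat`).
#' @return `path`, invisibly. Output is byte-deterministic for a given
#'   project.
#' @export
write_geocat <- function(project, path) {
  stopifnot(inherits(project, "geocat_project"))
  doc <- list(
    format_version = project$format_version,
    taxon_name = project$taxon_name,
    occurrences = occ_to_plain(project$occurrence_set),
    parameters = params_to_plain(project$parameters),
    results = project$results,
    app_state = project$app_state,
    provenance = project$occurrence_set$provenance
  )
  for (k in names(project$extra)) doc[[k]] <- project$extra[[k]]
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null",
                           pretty = 2)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(json, con, sep = "\n")
  invisible(path)
}

#' Read a `.geocat` project file
#'
#' @param path File path.
#' @return A [geocat_project()]. Required keys are `format_version`,
#'   `taxon_name`, `occurrences` and `parameters`; missing keys raise an
#'   error naming them, malformed JSON raises the parser error (with
#'   position). Top-level keys this version does not know are kept in
#'   `$extra` and written back verbatim by [write_geocat()].
#' @export
read_geocat <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  required <- c("format_version", "taxon_name", "occurrences", "parameters")
  miss <- setdiff(required, names(doc))
  if (length(miss)) {
    stop("not a valid .geocat file; missing required key(s): ",
         paste(miss, collapse = ", "))
  }
  prov <- doc$provenance
  if (is.null(prov)) prov <- list()
  prov <- lapply(prov, function(x) {
    if (!is.list(x)) return(x)
    u <- unlist(x)
    if (is.null(u)) character(0) else u
  })
  if (is.null(prov$audit)) prov$audit <- character(0)
  known <- c(required, "results", "app_state", "provenance")
  extra <- doc[setdiff(names(doc), known)]
  geocat_project(
    occurrence_set = plain_to_occ(doc$occurrences, doc$taxon_name, prov),
    parameters = plain_to_params(doc$parameters),
    results = doc$results,
    app_state = if (is.null(doc$app_state)) list() else doc$app_state,
    taxon_name = doc$taxon_name,
    extra = extra
  )
}
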