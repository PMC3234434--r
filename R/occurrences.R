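#' Construct a set of species occurrence records
#'
#' An occurrence set is the in-memory model of the georeferenced records for a
#' single taxon: decimal latitude/longitude in WGS84 degrees plus the flags
#' that drive the assessment workflow. Each record carries a `visible` flag
#' (does it participate in analysis?) and an `edited` flag (have its
#' coordinates been changed since load?). Filters and validation only ever
#' toggle `visible`; [edit_point()] with `action = "move"` is the sole
#' operation that changes coordinates.
#'
#' @param taxon Taxon name (single string).
#' @param lat,lon Numeric vectors of decimal degrees (WGS84). `NA` is allowed
#'   and is flagged by [validate_occurrences()].
#' @param id Optional character vector of unique record identifiers; defaults
#'   to `"occ-1"`, `"occ-2"`, ...
#' @param source Record provenance, one of `"user"`, `"csv"`, `"gbif"`,
#'   `"flickr"`, `"scratchpad"` (recycled).
#' @param visible,edited Logical vectors (recycled).
#' @param uncertainty_m Optional non-negative coordinate uncertainty in
#'   metres (`NA` = not recorded).
#' @param metadata Optional list (one element per record) of named character
#'   vectors with free-form attributes (collector, date, locality, ...).
#' @param provenance Named list describing where the set came from (source
#'   file, caps applied). The audit trail of edits lives in
#'   `provenance$audit`.
#'
#' @return An object of class `occurrence_set`: a list with elements `taxon`,
#'   `records` (a data frame with columns `id`, `lat`, `lon`, `source`,
#'   `visible`, `edited`, `uncertainty_m` and list-column `metadata`) and
#'   `provenance`.
#' @seealso [validate_occurrences()], [filter_bbox()], [filter_precision()],
#'   [edit_point()]
#' @export
#' @examples
#' occ <- occurrence_set("Aloe demo", lat = c(-1.2, -1.3), lon = c(36.8, 36.9))
#' occ
occurrence_set <- function(taxon, lat, lon, id = NULL,
                           source = "user", visible = TRUE, edited = FALSE,
                           uncertainty_m = NA_real_, metadata = NULL,
                           provenance = list()) {
  stopifnot(is.character(taxon), length(taxon) == 1L)
  n <- length(lat)
  if (length(lon) != n) stop("lat and lon must have the same length")
  if (is.null(id)) {
    id <- if (n) paste0("occ-", seq_len(n)) else character(0)
  }
  id <- as.character(id)
  if (anyDuplicated(id)) stop("occurrence ids must be unique")
  source <- rep_len(as.character(source), n)
  bad <- setdiff(unique(source), occ_sources())
  if (length(bad)) {
    stop("unknown source(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(occ_sources(), collapse = ", "), ")")
  }
  uncertainty_m <- rep_len(as.numeric(uncertainty_m), n)
  if (any(uncertainty_m < 0, na.rm = TRUE)) {
    stop("uncertainty_m must be non-negative")
  }
  if (is.null(metadata)) metadata <- rep(list(character(0)), n)
  if (length(metadata) != n) stop("metadata must have one element per record")
  records <- data.frame(
    id = id,
    lat = as.numeric(lat),
    lon = as.numeric(lon),
    source = source,
    visible = rep_len(as.logical(visible), n),
    edited = rep_len(as.logical(edited), n),
    uncertainty_m = uncertainty_m,
    stringsAsFactors = FALSE
  )
  records$metadata <- metadata
  if (is.null(provenance$audit)) provenance$audit <- character(0)
  new_occurrence_set(taxon, records, provenance)
}

occ_sources <- function() c("user", "csv", "gbif", "flickr", "scratchpad")

new_occurrence_set <- function(taxon, records, provenance) {
  structure(list(taxon = taxon, records = records, provenance = provenance),
            class = "occurrence_set")
}

#' @export
print.occurrence_set <- function(x, ...) {
  r <- x$records
  cat(sprintf("<occurrence_set> %s: %d records (%d visible, %d edited)\n",
              x$taxon, nrow(r), sum(r$visible), sum(r$edited)))
  if (length(x$provenance$audit)) {
    cat(sprintf("  audit trail: %d edit(s)\n", length(x$provenance$audit)))
  }
  invisible(x)
}

#' Number of records in an occurrence set
#' @param x An `occurrence_set`.
#' @export
length.occurrence_set <- function(x) nrow(x$records)

append_audit <- function(set, entry) {
  set$provenance$audit <- c(set$provenance$audit, entry)
  set
}

#' Validate occurrence coordinates
#'
#' Screens a set for the georeferencing mistakes that routinely contaminate
#' aggregated occurrence data: missing coordinates, coordinates outside the
#' WGS84 domain, suspected latitude/longitude swaps, and exact coordinate
#' duplicates. Records with missing or out-of-range coordinates (including
#' suspected swaps) are hidden from analysis; duplicates are merely reported
#' and stay visible, since repeat collections at one site are legitimate.
#'
#' A record is a suspected lat/lon swap when `|lat| > 90` but `|lat| <= 180`,
#' i.e. the latitude is impossible but would be a legal longitude. Swaps are
#' flagged, never auto-corrected: deciding whether the pair is swapped or
#' simply wrong needs a human who knows the taxon.
#'
#' @param set An [occurrence_set()]; must be non-empty.
#' @return A `validation_report`: list with `counts` (named integer vector:
#'   `missing`, `out_of_range`, `suspected_swap`, `duplicate_pairs`), `flags`
#'   (data frame `id`, `reason`) and `set`, the input with offending records
#'   hidden.
#' @export
validate_occurrences <- function(set) {
  stopifnot(inherits(set, "occurrence_set"))
  r <- set$records
  if (nrow(r) == 0L) stop("no occurrences")

  missing <- is.na(r$lat) | is.na(r$lon)
  swap <- !missing & abs(r$lat) > 90 & abs(r$lat) <= 180 &
    !is.na(r$lon) & abs(r$lon) <= 180
  out <- !missing & !swap &
    (abs(r$lat) > 90 | abs(r$lon) > 180)

  # exact-duplicate coordinate pairs among records with usable coordinates
  key <- ifelse(missing, NA_character_, paste(r$lat, r$lon, sep = "|"))
  tab <- table(key[!is.na(key)])
  dup_groups <- names(tab)[tab > 1L]
  dup <- !is.na(key) & key %in% dup_groups
  dup_pairs <- sum(choose(tab[tab > 1L], 2))

  reason <- character(0)
  ids <- character(0)
  add <- function(sel, code) {
    ids <<- c(ids, r$id[sel])
    reason <<- c(reason, rep(code, sum(sel)))
  }
  add(missing, "missing_coords")
  add(swap, "possible_latlon_swap")
  add(out, "out_of_range")
  add(dup, "duplicate_coords")

  set$records$visible <- r$visible & !(missing | swap | out)

  structure(list(
    counts = c(missing = sum(missing), out_of_range = sum(out),
               suspected_swap = sum(swap), duplicate_pairs = dup_pairs),
    flags = data.frame(id = ids, reason = reason, stringsAsFactors = FALSE),
    set = set
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  for (nm in names(x$counts)) cat(sprintf("  %-15s %d\n", nm, x$counts[[nm]]))
  invisible(x)
}

#' Filter occurrences by bounding box
#'
#' Applies a rectangular geographic filter, the programmatic equivalent of
#' drawing a box on a map. Containment is boundary-inclusive (`>= min`,
#' `<= max`) so a point lying exactly on the box edge counts as inside.
#'
#' @param set An [occurrence_set()].
#' @param bbox Named numeric vector or list with `min_lat`, `min_lon`,
#'   `max_lat`, `max_lon`.
#' @param mode `"hide_inside"`, `"hide_outside"` or `"delete_inside"`. The
#'   hide modes set `visible = FALSE`; delete removes the records.
#' @return The filtered `occurrence_set`.
#' @export
filter_bbox <- function(set, bbox,
                        mode = c("hide_inside", "hide_outside", "delete_inside")) {
  stopifnot(inherits(set, "occurrence_set"))
  mode <- match.arg(mode)
  need <- c("min_lat", "min_lon", "max_lat", "max_lon")
  if (!all(need %in% names(bbox))) {
    stop("bbox must have named elements ", paste(need, collapse = ", "))
  }
  b <- lapply(bbox[need], as.numeric)
  if (b$min_lat > b$max_lat || b$min_lon > b$max_lon) {
    stop("inverted bbox: min must not exceed max")
  }
  r <- set$records
  inside <- !is.na(r$lat) & !is.na(r$lon) &
    r$lat >= b$min_lat & r$lat <= b$max_lat &
    r$lon >= b$min_lon & r$lon <= b$max_lon
  if (mode == "hide_inside") {
    set$records$visible[inside] <- FALSE
  } else if (mode == "hide_outside") {
    set$records$visible[!inside] <- FALSE
  } else {
    set$records <- r[!inside, , drop = FALSE]
    rownames(set$records) <- NULL
  }
  set$provenance$filters <- c(
    set$provenance$filters,
    sprintf("bbox %s lat[%g,%g] lon[%g,%g]: %d record(s) affected",
            mode, b$min_lat, b$max_lat, b$min_lon, b$max_lon, sum(inside))
  )
  set
}

#' Filter occurrences by coordinate precision
#'
#' Hides records whose stated coordinate uncertainty exceeds a threshold.
#' Records without an uncertainty value pass unchanged: most herbarium and
#' museum records lack the field, and hiding them would silently discard the
#' bulk of typical datasets.
#'
#' @param set An [occurrence_set()].
#' @param max_uncertainty_m Positive threshold in metres.
#' @return The filtered `occurrence_set`. Warns when no record carries an
#'   uncertainty value (the filter is then a no-op).
#' @export
filter_precision <- function(set, max_uncertainty_m) {
  stopifnot(inherits(set, "occurrence_set"))
  if (!is.numeric(max_uncertainty_m) || length(max_uncertainty_m) != 1L ||
      is.na(max_uncertainty_m) || max_uncertainty_m <= 0) {
    stop("max_uncertainty_m must be a single positive number")
  }
  u <- set$records$uncertainty_m
  if (all(is.na(u))) {
    warning("no record has a coordinate uncertainty; precision filter is a no-op")
    return(set)
  }
  hide <- !is.na(u) & u > max_uncertainty_m
  set$records$visible[hide] <- FALSE
  set$provenance$filters <- c(
    set$provenance$filters,
    sprintf("precision > %g m: %d record(s) hidden", max_uncertainty_m, sum(hide))
  )
  set
}

#' Edit a single occurrence record
#'
#' The point-level editing operations of the assessment workflow: move a
#' point to corrected coordinates, delete it, or toggle its participation in
#' analysis. Every edit is appended to the audit trail in
#' `provenance$audit`, so a reviewer can see exactly which records were
#' touched. `move` is the only operation that changes coordinates and always
#' sets `edited = TRUE`.
#'
#' @param set An [occurrence_set()].
#' @param id Record identifier; must exist in the set.
#' @param action One of `"move"`, `"delete"`, `"hide"`, `"show"`.
#' @param new_coords For `move`: numeric `c(lat, lon)` within the WGS84
#'   domain.
#' @return The edited `occurrence_set`.
#' @export
edit_point <- function(set, id, action = c("move", "delete", "hide", "show"),
                       new_coords = NULL) {
  stopifnot(inherits(set, "occurrence_set"))
  action <- match.arg(action)
  i <- match(id, set$records$id)
  if (is.na(i)) stop("unknown id: ", id)
  if (action == "move") {
    if (is.null(new_coords) || length(new_coords) != 2L ||
        any(is.na(new_coords))) {
      stop("move requires new_coords = c(lat, lon)")
    }
    lat <- as.numeric(new_coords[[1]]); lon <- as.numeric(new_coords[[2]])
    if (abs(lat) > 90 || abs(lon) > 180) {
      stop("move with invalid coords: lat in [-90,90], lon in [-180,180]")
    }
    entry <- sprintf("move %s (%g,%g) -> (%g,%g)", id,
                     set$records$lat[i], set$records$lon[i], lat, lon)
    set$records$lat[i] <- lat
    set$records$lon[i] <- lon
    set$records$edited[i] <- TRUE
  } else if (action == "delete") {
    entry <- paste("delete", id)
    set$records <- set$records[-i, , drop = FALSE]
    rownames(set$records) <- NULL
  } else {
    set$records$visible[i] <- (action == "show")
    entry <- paste(action, id)
  }
  append_audit(set, entry)
}
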