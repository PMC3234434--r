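# CSV input/output for occurrence records.
#
# Two dialects: "generic" (comma-separated, latitude/longitude headers) and
# "gbif" (GBIF occurrence download: decimalLatitude/decimalLongitude,
# tab- or comma-delimited, detected from the header line). Column matching is
# case-insensitive. The writer emits a deterministic RFC-4180 file with
# degrees at 6 decimal places (~0.1 m), so write -> read -> write is
# byte-stable.

LAT_HEADERS <- c("latitude", "decimallatitude", "lat")
LON_HEADERS <- c("longitude", "decimallongitude", "lon")
UNC_HEADERS <- c("uncertainty_m", "coordinateuncertaintyinmeters")

#' Default per-source display caps
#'
#' Caps on the number of records loaded as visible per source, mirroring the
#' display limits of the aggregators: 500 for GBIF and 250 for Flickr; other
#' sources are uncapped. Rows beyond a cap are still loaded — with
#' `visible = FALSE` — so no data is lost.
#'
#' @return Named numeric vector of caps (0 means unlimited).
#' @export
default_source_caps <- function() c(gbif = 500, flickr = 250)

detect_delim <- function(path) {
  header <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

match_header <- function(headers, candidates) {
  hit <- which(tolower(headers) %in% candidates)
  if (length(hit)) hit[1] else NA_integer_
}

#' Read occurrence records from CSV
#'
#' Parses a generic or GBIF-download CSV into an [occurrence_set()]. Rows
#' whose coordinates cannot be parsed as numbers are skipped and counted in
#' `provenance$skipped_rows`. When a per-source cap applies, rows beyond the
#' cap (in file order) are loaded with `visible = FALSE` and a warning is
#' issued; the cap is recorded in `provenance`. Columns named `id`,
#' `source`, `visible`, `edited` and an uncertainty column are honoured when
#' present (so files written by [write_occurrence_csv()] round-trip); any
#' other column becomes record metadata, with a leading `meta_` prefix
#' stripped.
#'
#' @param path CSV file path.
#' @param dialect `"generic"` (comma-separated, `latitude`/`longitude`) or
#'   `"gbif"` (tab- or comma-delimited, `decimalLatitude`/
#'   `decimalLongitude`); either dialect accepts either header pair,
#'   case-insensitively.
#' @param caps Named per-source caps on visible records; see
#'   [default_source_caps()]. 0 disables a cap.
#' @param taxon Taxon name for the set; defaults to the file name.
#' @param default_source Source assigned to rows without a `source` column
#'   (`"gbif"` for the gbif dialect, `"csv"` otherwise).
#' @return An [occurrence_set()].
#' @export
read_occurrence_csv <- function(path, dialect = c("generic", "gbif"),
                                caps = default_source_caps(),
                                taxon = NULL,
                                default_source = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  delim <- if (dialect == "gbif") detect_delim(path) else ","
  raw <- utils::read.table(path, header = TRUE, sep = delim, quote = "\"",
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "",
                           na.strings = character(0))
  headers <- names(raw)
  lat_col <- match_header(headers, LAT_HEADERS)
  lon_col <- match_header(headers, LON_HEADERS)
  if (is.na(lat_col) || is.na(lon_col)) {
    stop("no coordinate columns: expected latitude/longitude or ",
         "decimalLatitude/decimalLongitude (case-insensitive)")
  }
  if (is.null(default_source)) {
    default_source <- if (dialect == "gbif") "gbif" else "csv"
  }
  if (is.null(taxon)) taxon <- sub("\\.[^.]*$", "", basename(path))

  lat <- suppressWarnings(as.numeric(raw[[lat_col]]))
  lon <- suppressWarnings(as.numeric(raw[[lon_col]]))
  keep <- !is.na(lat) & !is.na(lon)
  n_skipped <- sum(!keep)
  raw <- raw[keep, , drop = FALSE]
  lat <- lat[keep]; lon <- lon[keep]
  if (nrow(raw) == 0L) stop("no rows with parseable coordinates in ", path)

  col <- function(cands) {
    k <- match_header(headers, cands)
    if (is.na(k)) NULL else raw[[k]]
  }
  id <- col("id")
  if (is.null(id) || anyDuplicated(id)) id <- paste0("occ-", seq_len(nrow(raw)))
  src <- col("source")
  if (is.null(src)) src <- rep(default_source, nrow(raw))
  src[!src %in% occ_sources()] <- default_source
  visible <- col("visible")
  visible <- if (is.null(visible)) rep(TRUE, nrow(raw)) else toupper(visible) %in% c("TRUE", "T", "1")
  edited <- col("edited")
  edited <- if (is.null(edited)) rep(FALSE, nrow(raw)) else toupper(edited) %in% c("TRUE", "T", "1")
  unc <- col(UNC_HEADERS)
  unc <- if (is.null(unc)) rep(NA_real_, nrow(raw)) else suppressWarnings(as.numeric(unc))

  known <- c(LAT_HEADERS, LON_HEADERS, UNC_HEADERS,
             "id", "source", "visible", "edited")
  meta_cols <- headers[!tolower(headers) %in% known]
  metadata <- lapply(seq_len(nrow(raw)), function(i) {
    vals <- vapply(meta_cols, function(cn) raw[[cn]][i], character(1))
    vals <- vals[!is.na(vals) & nzchar(vals)]
    names(vals) <- sub("^meta_", "", names(vals))
    vals
  })

  prov <- list(source_file = basename(path), dialect = dialect,
               skipped_rows = n_skipped, audit = character(0))

  # per-source display caps: rows past the cap stay in the set but hidden
  for (s in names(caps)) {
    cap <- caps[[s]]
    if (is.na(cap) || cap <= 0) next
    idx <- which(src == s)
    if (length(idx) > cap) {
      over <- idx[-seq_len(cap)]
      visible[over] <- FALSE
      prov$caps_applied <- c(prov$caps_applied,
                             sprintf("%s: %d records over the %d display cap hidden",
                                     s, length(over), cap))
      warning(sprintf("%s returned %d records, more than the display cap of %d; %d loaded as hidden",
                      s, length(idx), cap, length(over)))
    }
  }

  occurrence_set(taxon = taxon, lat = lat, lon = lon, id = id, source = src,
                 visible = visible, edited = edited, uncertainty_m = unc,
                 metadata = metadata, provenance = prov)
}

csv_quote <- function(x) {
  need <- grepl('[",\n]', x)
  x[need] <- paste0('"', gsub('"', '""', x[need]), '"')
  x
}

fmt_deg <- function(x) ifelse(is.na(x), "", sprintf("%.6f", x))

fmt_num <- function(x) {
  ifelse(is.na(x), "", sub("\\.?0+$", "", sprintf("%.6f", x)))
}

#' Write occurrence records to CSV
#'
#' One row per occurrence with `id`, `lat`, `lon`, `source`, `visible`,
#' `edited`, `uncertainty_m` and one `meta_<key>` column per metadata key
#' present in the set. Degrees are written at 6 decimal places; output is
#' deterministic (fixed column order, `\n` line endings), and
#' [read_occurrence_csv()] restores the set including flags.
#'
#' @param set A non-empty [occurrence_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_occurrence_csv <- function(set, path) {
  stopifnot(inherits(set, "occurrence_set"))
  r <- set$records
  if (nrow(r) == 0L) stop("empty occurrence set")
  meta_keys <- sort(unique(as.character(unlist(lapply(r$metadata, names)))))
  header <- c("id", "lat", "lon", "source", "visible", "edited",
              "uncertainty_m",
              if (length(meta_keys)) paste0("meta_", meta_keys))
  rows <- vapply(seq_len(nrow(r)), function(i) {
    meta <- r$metadata[[i]]
    mv <- vapply(meta_keys, function(k) {
      if (k %in% names(meta)) meta[[k]] else ""
    }, character(1))
    paste(csv_quote(c(r$id[i], fmt_deg(r$lat[i]), fmt_deg(r$lon[i]),
                      r$source[i], as.character(r$visible[i]),
                      as.character(r$edited[i]), fmt_num(r$uncertainty_m[i]),
                      mv)), collapse = ",")
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(header, collapse = ","), rows), con, sep = "\n")
  invisible(path)
}
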