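# Preliminary IUCN Red List criterion-B rating from EOO and AOO.
#
# The threshold constants below are not an output of this package: they are
# the fixed range-size thresholds of criterion B in the IUCN Red List
# Categories and Criteria version 3.1 (2001) — B1 for extent of occurrence,
# B2 for area of occupancy. Comparison is strict less-than, so an area
# exactly on a threshold falls in the less-threatened category. A rating
# from these areas alone is preliminary: a full criterion-B listing also
# requires subcriteria (severe fragmentation / number of locations, decline,
# extreme fluctuation) that no range metric can establish by itself.

#' Criterion-B range-size thresholds (IUCN v3.1)
#'
#' @return Named list with numeric vectors `eoo` (B1) and `aoo` (B2), each
#'   giving the strict upper bounds in km² for `CR`, `EN` and `VU`.
#' @export
criterion_b_thresholds <- function() {
  list(
    eoo = c(CR = 100, EN = 5000, VU = 20000),
    aoo = c(CR = 10, EN = 500, VU = 2000)
  )
}

RATING_LEVELS <- c("CR", "EN", "VU", "LC_or_NT")

CAVEAT_NOTE <- paste(
  "Preliminary rating from range metrics only, subject to meeting the full",
  "requirements of the criteria (criterion-B subcriteria on fragmentation,",
  "locations, decline and fluctuation are not assessed)."
)

#' Rate one range metric against the criterion-B thresholds
#'
#' @param area_km2 Non-negative area in km².
#' @param metric `"eoo"` (criterion B1) or `"aoo"` (criterion B2).
#' @return One of `"CR"`, `"EN"`, `"VU"`, `"LC_or_NT"`. Thresholds are
#'   strict: `rate_metric(100, "eoo")` is `"EN"`, not `"CR"`.
#' @export
rate_metric <- function(area_km2, metric = c("eoo", "aoo")) {
  metric <- match.arg(metric)
  if (!is.numeric(area_km2) || length(area_km2) != 1L || is.na(area_km2) ||
      area_km2 < 0) {
    stop("area_km2 must be a single non-negative number")
  }
  th <- criterion_b_thresholds()[[metric]]
  below <- which(area_km2 < th)
  if (length(below)) names(th)[below[1]] else "LC_or_NT"
}

#' Consolidated preliminary criterion-B rating
#'
#' Rates EOO against B1 and AOO against B2 and reports the more threatened
#' of the two, since a taxon qualifying under either subcriterion qualifies
#' for the category. A degenerate EOO (fewer than 3 non-collinear points, so
#' no hull area exists) is excluded rather than rated as 0 km², because a
#' zero-area hull reflects sample size, not range size; optionally
#' `eoo_floor_aoo = TRUE` applies the convention that EOO is never smaller
#' than AOO and rates the AOO area under B1 as well.
#'
#' @param eoo An [compute_eoo()] result.
#' @param aoo An [compute_aoo()] result.
#' @param eoo_floor_aoo Treat a degenerate EOO as equal to the AOO area
#'   (default `FALSE`: degenerate EOO is reported as not applicable and the
#'   preliminary rating comes from AOO alone).
#' @return An object of class `preliminary_rating`: list with
#'   `eoo_category`, `aoo_category`, `preliminary` (the most threatened of
#'   the applicable categories) and `caveat_note`.
#' @export
preliminary_rating <- function(eoo, aoo, eoo_floor_aoo = FALSE) {
  stopifnot(inherits(eoo, "eoo_result"), inherits(aoo, "aoo_result"))
  aoo_cat <- rate_metric(aoo$area_km2, "aoo")
  if (eoo$degenerate && !eoo_floor_aoo) {
    eoo_cat <- "not_applicable"
    prelim <- aoo_cat
  } else {
    eoo_area <- if (eoo$degenerate) aoo$area_km2 else eoo$area_km2
    eoo_cat <- rate_metric(eoo_area, "eoo")
    prelim <- worst_category(eoo_cat, aoo_cat)
  }
  structure(list(
    eoo_category = eoo_cat,
    aoo_category = aoo_cat,
    preliminary = prelim,
    caveat_note = CAVEAT_NOTE
  ), class = "preliminary_rating")
}

worst_category <- function(...) {
  cats <- c(...)
  cats <- cats[cats %in% RATING_LEVELS]
  RATING_LEVELS[min(match(cats, RATING_LEVELS))]
}

#' @export
print.preliminary_rating <- function(x, ...) {
  cat(sprintf("<preliminary_rating> %s (EOO %s, AOO %s)\n",
              x$preliminary, x$eoo_category, x$aoo_category))
  cat("  ", x$caveat_note, "\n", sep = "")
  invisible(x)
}
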