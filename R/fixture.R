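# Seeded synthetic occurrence sets, so every analysis path can be exercised
# without downloading real records. Two spatial patterns: uniform scatter
# over a box, or Gaussian clusters mimicking the clumped collecting
# localities typical of herbarium data. Optional injected defects (swapped
# lat/lon, missing coordinates, exact duplicates) emulate the georeferencing
# mistakes the validator screens for.

#' Generate a synthetic occurrence set
#'
#' The default extent is a 2 x 2 degree equatorial box with longitudes above
#' 90 degrees, so an injected lat/lon swap produces an impossible latitude
#' and is detectable by [validate_occurrences()] — mirroring how real swaps
#' reveal themselves. Coordinates are rounded to 6 decimal places (about
#' 0.1 m, typical GPS precision), which also makes file round trips exact.
#' The generator draws from R's RNG under the given seed and restores the
#' caller's RNG state afterwards.
#'
#' @param n Number of records (>= 1).
#' @param pattern `"gaussian_clusters"` (3 cluster centres drawn inside the
#'   extent, points scattered around them with sd 5% of the extent span) or
#'   `"uniform_box"`.
#' @param extent Named vector `c(min_lat, min_lon, max_lat, max_lon)` in
#'   degrees.
#' @param seed Integer seed; the same seed always yields the identical set.
#' @param swap_rate,missing_rate,duplicate_rate Fractions of records (each
#'   rounded to a count) given the corresponding defect: lat/lon exchanged,
#'   latitude set to `NA`, coordinates copied from another record. Defects
#'   are applied to disjoint records.
#' @param taxon Taxon name for the set.
#' @return An [occurrence_set()]; `provenance` records the generator
#'   parameters, including the ids of defect-injected records.
#' @export
generate_fixture <- function(n,
                             pattern = c("gaussian_clusters", "uniform_box"),
                             extent = c(min_lat = -1, min_lon = 110,
                                        max_lat = 1, max_lon = 112),
                             seed = 42,
                             swap_rate = 0, missing_rate = 0,
                             duplicate_rate = 0,
                             taxon = "Synthetic taxon") {
  pattern <- match.arg(pattern)
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1) {
    stop("n must be >= 1")
  }
  n <- as.integer(n)
  need <- c("min_lat", "min_lon", "max_lat", "max_lon")
  if (!all(need %in% names(extent))) {
    stop("extent must have named elements ", paste(need, collapse = ", "))
  }
  e <- as.list(extent[need])
  stopifnot(e$min_lat < e$max_lat, e$min_lon < e$max_lon)

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  dlat <- e$max_lat - e$min_lat
  dlon <- e$max_lon - e$min_lon
  if (pattern == "uniform_box") {
    lat <- stats::runif(n, e$min_lat, e$max_lat)
    lon <- stats::runif(n, e$min_lon, e$max_lon)
  } else {
    k <- 3L
    # cluster centres kept off the extent edge so most points stay inside
    c_lat <- stats::runif(k, e$min_lat + 0.1 * dlat, e$max_lat - 0.1 * dlat)
    c_lon <- stats::runif(k, e$min_lon + 0.1 * dlon, e$max_lon - 0.1 * dlon)
    pick <- sample.int(k, n, replace = TRUE)
    lat <- stats::rnorm(n, c_lat[pick], 0.05 * dlat)
    lon <- stats::rnorm(n, c_lon[pick], 0.05 * dlon)
  }
  lat <- round6(pmin(pmax(lat, -90), 90))
  lon <- round6(pmin(pmax(lon, -180), 180))

  n_swap <- round(swap_rate * n)
  n_missing <- round(missing_rate * n)
  n_dup <- round(duplicate_rate * n)
  if (n_swap + n_missing + n_dup > n) {
    stop("defect rates sum to more than one defect per record")
  }
  idx <- sample.int(n, n_swap + n_missing + n_dup)
  swap_idx <- idx[seq_len(n_swap)]
  missing_idx <- idx[n_swap + seq_len(n_missing)]
  dup_idx <- idx[n_swap + n_missing + seq_len(n_dup)]

  if (n_swap) {
    tmp <- lat[swap_idx]
    lat[swap_idx] <- lon[swap_idx]
    lon[swap_idx] <- tmp
  }
  if (n_missing) lat[missing_idx] <- NA_real_
  if (n_dup) {
    clean <- setdiff(seq_len(n), idx)
    src <- if (length(clean)) {
      clean[(seq_len(n_dup) - 1L) %% length(clean) + 1L]
    } else rep(1L, n_dup)
    lat[dup_idx] <- lat[src]
    lon[dup_idx] <- lon[src]
  }

  id <- sprintf("occ-%03d", seq_len(n))
  occurrence_set(
    taxon = taxon, lat = lat, lon = lon, id = id, source = "user",
    provenance = list(
      generator = "conrange::generate_fixture",
      pattern = pattern, n = n, seed = seed,
      extent = paste(sprintf("%s=%g", need, unlist(e)), collapse = " "),
      swapped_ids = id[sort(swap_idx)],
      missing_ids = id[sort(missing_idx)],
      duplicate_ids = id[sort(dup_idx)],
      audit = character(0)
    )
  )
}
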