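# Per-dataset cylindrical equal-area projection.
#
# EOO and AOO are areas in km^2, so hull and grid computations must happen in
# a planar frame that preserves area. We use a Lambert cylindrical equal-area
# projection on the authalic sphere, centred on the data: lon0 at the
# midpoint of the (seam-adjusted) longitude range and the standard parallel
# at the mean latitude, which keeps shape distortion small where the points
# actually are. Forward mapping, with phi/lambda in radians:
#
#   x = R * (lambda - lambda0) * cos(phi_ts)
#   y = R * sin(phi) / cos(phi_ts)
#
# Planar areas in this frame equal spherical areas on the authalic sphere.

AUTHALIC_RADIUS_KM <- 6371.0072

#' Projection parameters for the equal-area frame
#'
#' @param lon0 Central meridian in degrees.
#' @param lat_ts Standard parallel (latitude of true scale) in degrees.
#' @param R Sphere radius in km; the default is the authalic Earth radius, so
#'   planar areas equal true surface areas.
#' @return An object of class `projection_params`.
#' @export
projection_params <- function(lon0, lat_ts, R = AUTHALIC_RADIUS_KM) {
  stopifnot(is.numeric(lon0), is.numeric(lat_ts), R > 0)
  # a standard parallel at the pole degenerates the projection; datasets that
  # extreme are clamped to keep cos(lat_ts) bounded away from zero
  lat_ts <- max(min(lat_ts, 89.9), -89.9)
  structure(list(lon0 = norm_lon(lon0), lat_ts = lat_ts, R = R),
            class = "projection_params")
}

# wrap a longitude into (-180, 180]
norm_lon <- function(lon) {
  out <- ((lon + 180) %% 360) - 180
  out[out == -180] <- 180
  out
}

#' Forward equal-area projection
#'
#' @param lat,lon Numeric degree vectors.
#' @param params A [projection_params()].
#' @return Data frame with columns `x`, `y` in km.
#' @export
project_forward <- function(lat, lon, params) {
  stopifnot(inherits(params, "projection_params"))
  k <- cos(params$lat_ts * pi / 180)
  dlon <- norm_lon(lon - params$lon0)
  data.frame(
    x = params$R * (dlon * pi / 180) * k,
    y = params$R * sin(lat * pi / 180) / k
  )
}

#' Inverse equal-area projection
#'
#' @param x,y Numeric km vectors in the projected frame.
#' @param params A [projection_params()].
#' @return Data frame with columns `lat`, `lon` in degrees.
#' @export
project_inverse <- function(x, y, params) {
  stopifnot(inherits(params, "projection_params"))
  k <- cos(params$lat_ts * pi / 180)
  s <- pmin(pmax(y * k / params$R, -1), 1)
  data.frame(
    lat = asin(s) * 180 / pi,
    lon = norm_lon(params$lon0 + (x / (params$R * k)) * 180 / pi)
  )
}

# Longitudinal span handling: longitudes live on a circle, so the usable
# extent of a point set is 360 minus the largest empty gap between adjacent
# longitudes. Returns list(extent, lon0) where lon0 is the midpoint of the
# occupied arc, or errors when the set spans >= 180 degrees (a planar hull
# would be meaningless there).
lon_arc_center <- function(lon) {
  lon <- norm_lon(lon)
  u <- sort(unique(lon))
  if (length(u) == 1L) return(list(extent = 0, lon0 = u))
  gaps <- c(diff(u), 360 - (u[length(u)] - u[1]))
  gi <- which.max(gaps)
  extent <- 360 - gaps[gi]
  if (extent >= 180) {
    stop("longitudinal extent >= 180 degrees: range too wide for planar analysis")
  }
  start <- if (gi == length(u)) u[1] else u[gi + 1]
  list(extent = extent, lon0 = norm_lon(start + extent / 2))
}

#' Project the visible occurrences of a set into the equal-area frame
#'
#' Chooses projection parameters from the data (central meridian at the
#' midpoint of the longitude range after seam adjustment, standard parallel
#' at the mean latitude) and maps every visible record to planar km
#' coordinates. Point sets straddling the antimeridian are recentred
#' transparently; sets spanning 180 degrees of longitude or more are refused
#' rather than analysed in a frame where the hull would be misleading.
#'
#' @param set An [occurrence_set()] with at least one visible record with
#'   valid coordinates.
#' @param params Optional [projection_params()] to reuse (e.g. from a saved
#'   project); by default parameters are derived from the data.
#' @return An object of class `projected_points`: list with `points` (data
#'   frame `id`, `x`, `y`; one row per visible occurrence) and `params`.
#' @export
project_points <- function(set, params = NULL) {
  stopifnot(inherits(set, "occurrence_set"))
  r <- set$records
  # longitudes are 360-periodic; normalise before the validity screen so a
  # set shifted by full turns projects identically
  r$lon <- norm_lon(r$lon)
  keep <- r$visible & !is.na(r$lat) & !is.na(r$lon) & abs(r$lat) <= 90
  if (!any(keep)) stop("no visible occurrences with valid coordinates")
  r <- r[keep, , drop = FALSE]
  if (is.null(params)) {
    arc <- lon_arc_center(r$lon)
    params <- projection_params(lon0 = arc$lon0, lat_ts = mean(r$lat))
  } else {
    lon_arc_center(r$lon)  # still refuse over-wide sets
  }
  xy <- project_forward(r$lat, r$lon, params)
  structure(list(
    points = data.frame(id = r$id, x = xy$x, y = xy$y,
                        stringsAsFactors = FALSE),
    params = params
  ), class = "projected_points")
}

#' @export
print.projected_points <- function(x, ...) {
  cat(sprintf("<projected_points> %d points; lon0=%.4f lat_ts=%.4f R=%.4f km\n",
              nrow(x$points), x$params$lon0, x$params$lat_ts, x$params$R))
  invisible(x)
}
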