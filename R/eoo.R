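# Extent of occurrence: convex hull of the projected occurrences.
#
# The hull is computed with the quickhull divide-and-conquer algorithm:
# split the points by the chord between the two x-extreme points, then on
# each side recursively take the point farthest from the chord and keep only
# points outside the triangle it forms. The output is the STRICT hull —
# collinear boundary points are not vertices — in canonical counter-clockwise
# order starting from the lowest-x (then lowest-y) vertex, so identical point
# sets always yield byte-identical results.

# cross product (b - a) x (p - a); > 0 when p is strictly left of a -> b
cross2 <- function(a, b, p) {
  (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
}

#' Convex hull of planar points by quickhull
#'
#' @param points Two-column numeric matrix or data frame of `(x, y)`
#'   coordinates in km. Duplicate points are removed before the hull is
#'   built.
#' @return Numeric matrix of hull vertices (columns `x`, `y`), a subset of
#'   the input points, ordered counter-clockwise starting from the vertex
#'   with the lowest x (ties broken by lowest y). Degenerate inputs return
#'   fewer than 3 rows: a single point for one unique location, the two
#'   extreme endpoints for collinear sets.
#' @export
#' @examples
#' quickhull(rbind(c(0, 0), c(4, 0), c(4, 4), c(0, 4), c(2, 2)))
quickhull <- function(points) {
  pts <- as.matrix(points)
  if (length(pts) == 0L || nrow(pts) == 0L) stop("empty input: no points")
  if (ncol(pts) != 2L) stop("points must have two columns (x, y)")
  if (any(!is.finite(pts))) stop("points must be finite")
  pts <- unique(pts)
  dimnames(pts) <- list(NULL, c("x", "y"))
  n <- nrow(pts)
  if (n == 1L) return(pts)

  ord <- order(pts[, 1], pts[, 2])
  a <- pts[ord[1], ]   # lowest x, then lowest y
  b <- pts[ord[n], ]   # highest x, then highest y

  side <- apply(pts, 1, function(p) cross2(a, b, p))
  upper <- pts[side > 0, , drop = FALSE]
  lower <- pts[side < 0, , drop = FALSE]

  if (nrow(upper) == 0L && nrow(lower) == 0L) {
    # all points collinear: hull degenerates to the two extreme endpoints
    return(rbind(a, b, deparse.level = 0))
  }

  # recursion: points strictly outside chord p -> q, keep the farthest
  find_hull <- function(s, p, q) {
    if (nrow(s) == 0L) return(NULL)
    d <- apply(s, 1, function(pt) cross2(p, q, pt))
    far <- s[which.max(d), ]
    s1 <- s[apply(s, 1, function(pt) cross2(p, far, pt)) > 0, , drop = FALSE]
    s2 <- s[apply(s, 1, function(pt) cross2(far, q, pt)) > 0, , drop = FALSE]
    rbind(find_hull(s1, p, far), matrix(far, 1, 2), find_hull(s2, far, q))
  }

  # clockwise walk: a -> (points left of a->b) -> b -> (points left of b->a)
  hull <- rbind(matrix(a, 1, 2), find_hull(upper, a, b),
                matrix(b, 1, 2), find_hull(lower, b, a))
  colnames(hull) <- c("x", "y")
  # canonical orientation: counter-clockwise, first vertex stays the lowest-x
  if (shoelace_signed(hull) < 0) {
    hull <- hull[c(1L, rev(seq_len(nrow(hull))[-1L])), , drop = FALSE]
  }
  hull
}

shoelace_signed <- function(v) {
  n <- nrow(v)
  if (n < 3L) return(0)
  j <- c(2:n, 1L)
  sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2]) / 2
}

#' Area of a simple polygon (shoelace formula)
#'
#' @param vertices Two-column matrix or data frame of polygon vertices in km,
#'   in order (either orientation); the closing edge is implicit.
#' @return Area in km²; `0` for fewer than 3 vertices.
#' @export
polygon_area <- function(vertices) {
  v <- as.matrix(vertices)
  if (length(v) == 0L || nrow(v) < 3L) return(0)
  abs(shoelace_signed(v))
}

#' Extent of occurrence (EOO) of a projected point set
#'
#' EOO measures the geographic range of a taxon as the area of the smallest
#' convex polygon containing every occurrence — the convex hull of the
#' visible, projected points. Fewer than three non-collinear points cannot
#' enclose an area; such sets are reported with area 0 and `degenerate =
#' TRUE`, and the rating step decides how to treat them.
#'
#' @param projected A [project_points()] result.
#' @return An object of class `eoo_result`: list with `hull` (vertex matrix
#'   in km, canonical CCW order), `area_km2`, `n_points_used` and
#'   `degenerate`.
#' @export
compute_eoo <- function(projected) {
  stopifnot(inherits(projected, "projected_points"))
  pts <- as.matrix(projected$points[, c("x", "y")])
  hull <- quickhull(pts)
  area <- polygon_area(hull)
  structure(list(
    hull = hull,
    area_km2 = area,
    n_points_used = nrow(pts),
    degenerate = nrow(hull) < 3L
  ), class = "eoo_result")
}

#' @export
print.eoo_result <- function(x, ...) {
  cat(sprintf("<eoo_result> area %.4f km2; %d hull vertices; %d points%s\n",
              x$area_km2, nrow(x$hull), x$n_points_used,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}
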