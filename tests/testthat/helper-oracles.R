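# Independent oracles, deliberately implemented with different algorithms
# than the package: gift-wrapping for the hull, fan triangulation for areas,
# rectangle containment for grid occupancy, a double loop for the diameter.

# Jarvis gift-wrapping march; strict hull (collinear ties resolved by
# taking the farthest candidate). Returns vertices as a matrix.
oracle_hull <- function(pts) {
  pts <- unique(as.matrix(pts))
  n <- nrow(pts)
  if (n <= 2L) return(pts)
  crossp <- function(o, a, b) {
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  }
  start <- order(pts[, 1], pts[, 2])[1]
  hull <- integer(0)
  cur <- start
  repeat {
    hull <- c(hull, cur)
    cand <- setdiff(seq_len(n), cur)
    q <- cand[1]
    for (r in cand[-1]) {
      cr <- crossp(pts[cur, ], pts[q, ], pts[r, ])
      d_r <- sum((pts[r, ] - pts[cur, ])^2)
      d_q <- sum((pts[q, ] - pts[cur, ])^2)
      if (cr < 0 || (cr == 0 && d_r > d_q)) q <- r
    }
    if (q == start) break
    cur <- q
    if (length(hull) > n) stop("gift wrapping failed to terminate")
  }
  pts[hull, , drop = FALSE]
}

# canonical form for orientation-insensitive vertex-set comparison
sort_rows <- function(m) {
  m <- as.matrix(m)
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

# polygon area by fan triangulation from the first vertex
oracle_fan_area <- function(v) {
  v <- as.matrix(v)
  n <- nrow(v)
  if (n < 3L) return(0)
  tri <- function(a, b, c) {
    ((b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])) / 2
  }
  abs(sum(vapply(2:(n - 1), function(k) tri(v[1, ], v[k, ], v[k + 1, ]),
                 numeric(1))))
}

# occupied cells by explicit rectangle containment over the index bounding
# box; half-open cells [i*w, (i+1)*w)
oracle_aoo_cells <- function(pts, w) {
  pts <- as.matrix(pts)
  is_ <- seq(floor(min(pts[, 1]) / w), floor(max(pts[, 1]) / w))
  js_ <- seq(floor(min(pts[, 2]) / w), floor(max(pts[, 2]) / w))
  out <- NULL
  for (i in is_) {
    for (j in js_) {
      inside <- pts[, 1] >= i * w & pts[, 1] < (i + 1) * w &
        pts[, 2] >= j * w & pts[, 2] < (j + 1) * w
      if (any(inside)) {
        out <- rbind(out, c(i = i, j = j, count = sum(inside)))
      }
    }
  }
  out <- as.data.frame(out)
  out$count <- as.integer(out$count)
  out <- out[order(out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  out
}

oracle_max_dist <- function(pts) {
  pts <- as.matrix(pts)
  best <- 0
  for (a in seq_len(nrow(pts) - 1)) {
    for (b in (a + 1):nrow(pts)) {
      best <- max(best, sqrt(sum((pts[a, ] - pts[b, ])^2)))
    }
  }
  best
}

# closed-form spherical area of the zone lambda in [l1,l2], phi in [p1,p2]
# (degrees) on a sphere of radius R
zone_area <- function(l1, l2, p1, p2, R) {
  R^2 * (l2 - l1) * pi / 180 * (sin(p2 * pi / 180) - sin(p1 * pi / 180))
}
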