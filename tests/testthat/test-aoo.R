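make_projected <- function(x, y) {
  structure(list(points = data.frame(id = paste0("p", seq_along(x)),
                                     x = x, y = y),
                 params = projection_params(0, 0)),
            class = "projected_points")
}

test_that("maximum pairwise distance matches hand values and the brute oracle", {
  expect_equal(max_pairwise_distance(rbind(c(0, 0), c(3, 4))), 5)
  expect_equal(max_pairwise_distance(rbind(c(1, 1), c(1, 1), c(1, 1))), 0)
  expect_error(max_pairwise_distance(rbind(c(0, 0))), "at least 2")
  set.seed(505)
  pts <- matrix(runif(200, -50, 50), ncol = 2)
  expect_equal(max_pairwise_distance(pts), oracle_max_dist(pts))
})

test_that("cell-width rules resolve to 2 km, the user width, or a tenth of the diameter", {
  expect_equal(resolve_cell_width(cell_width_rule("default")), 2)
  expect_equal(resolve_cell_width(cell_width_rule("user", 3.5)), 3.5)
  expect_error(cell_width_rule("user", -1), "positive")
  expect_error(cell_width_rule("user"), "positive")

  pts <- rbind(c(0, 0), c(60, 80))  # diameter 100 km
  expect_equal(resolve_cell_width(cell_width_rule("tenth_max_dist"), pts), 10)
  same <- rbind(c(5, 5), c(5, 5))
  expect_warning(w <- resolve_cell_width(cell_width_rule("tenth_max_dist"), same),
                 "coincident")
  expect_equal(w, 2)
})

test_that("points snap to the lower-left cell corner, half-open and with true floor", {
  pp <- make_projected(c(0.5, 1.9, 2.1), c(0.5, 1.9, 0.3))
  aoo <- compute_aoo(pp, 2)
  expect_equal(aoo$cells, data.frame(i = c(0, 1), j = c(0, 0),
                                     count = c(2L, 1L)))
  expect_equal(aoo$n_cells, 2)
  expect_equal(aoo$area_km2, 8)

  # snap formula: floor(x/w)*w gives the lower-left corner
  expect_equal(floor(5.3 / 2) * 2, 4)
  aoo2 <- compute_aoo(make_projected(5.3, 0.1), 2)
  expect_equal(aoo2$cells$i * aoo2$cell_width_km, 4)

  # boundary point belongs to the higher cell; negatives use true floor
  b <- compute_aoo(make_projected(c(2, -0.1, -2), c(0, 0, 0)), 2)
  expect_equal(b$cells$i, c(-1, 1))
  expect_equal(b$cells$count, c(2L, 1L))

  one <- compute_aoo(make_projected(0.3, 0.4), 2)
  expect_equal(one$n_cells, 1)
  expect_equal(one$area_km2, 4)
})

test_that("occupancy matches the rectangle-containment oracle on random sets", {
  set.seed(606)
  for (k in 1:100) {
    n <- sample(2:40, 1)
    pts <- matrix(runif(2 * n, -30, 30), ncol = 2)
    w <- runif(1, 0.5, 8)
    aoo <- compute_aoo(make_projected(pts[, 1], pts[, 2]), w)
    expect_equal(aoo$cells, oracle_aoo_cells(pts, w), ignore_attr = TRUE)
    expect_equal(sum(aoo$cells$count), n)
    expect_true(aoo$n_cells >= 1 && aoo$n_cells <= n)
    expect_equal(aoo$area_km2, aoo$n_cells * w^2)
  }
})

test_that("occupancy is invariant under whole-cell translations and point order", {
  set.seed(607)
  pts <- matrix(runif(50, 0, 20), ncol = 2)
  w <- 2.5
  a0 <- compute_aoo(make_projected(pts[, 1], pts[, 2]), w)
  shifted <- compute_aoo(make_projected(pts[, 1] + 3 * w, pts[, 2] - 7 * w), w)
  expect_equal(shifted$cells$count, a0$cells$count)
  expect_equal(shifted$cells$i, a0$cells$i + 3)
  expect_equal(shifted$cells$j, a0$cells$j - 7)
  perm <- sample(nrow(pts))
  expect_equal(compute_aoo(make_projected(pts[perm, 1], pts[perm, 2]), w)$cells,
               a0$cells)
  # adding a point never decreases the cell count
  grown <- compute_aoo(make_projected(c(pts[, 1], 100), c(pts[, 2], 100)), w)
  expect_gte(grown$n_cells, a0$n_cells)
})
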