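test_that("ESH matches a brute-force cell enumeration oracle", {
  # 10 x 10 grid of 1 km cells; range = left half; 30 forest cells in the
  # left half of which 5 sit above the species' elevation ceiling
  g <- grid_spec(10, 10, 1000)
  set.seed(71)
  forest <- matrix(FALSE, 10, 10)
  left_cells <- which(col(forest) <= 5)
  forest[sample(left_cells, 30)] <- TRUE
  elevation <- matrix(100, 10, 10)
  high <- sample(which(forest & col(forest) <= 5), 5)
  elevation[high] <- 900
  sp <- make_species("oracle", rect_ring(0, 0, 5000, 10000),
                     elev_min = 0, elev_max = 500)
  esh <- compute_esh(sp, forest, elevation, g)

  # oracle: enumerate every cell and test each condition directly
  cc <- cell_centers(g)
  expected <- 0
  for (i in 1:10) for (j in 1:10) {
    in_range <- cc$x[i, j] >= 0 && cc$x[i, j] <= 5000 &&
                cc$y[i, j] >= 0 && cc$y[i, j] <= 10000
    if (in_range && forest[i, j] &&
        elevation[i, j] >= 0 && elevation[i, j] <= 500)
      expected <- expected + 1
  }
  expect_equal(expected, 25)        # 30 forest cells minus the 5 high ones
  expect_equal(esh$area, expected * 1)   # 1 km^2 cells
  expect_equal(sum(esh$mask), expected)
})

test_that("ESH trivial cases and the elevation-clip skip", {
  g <- grid_spec(8, 8, 1000)
  forest <- matrix(TRUE, 8, 8)
  flat <- matrix(50, 8, 8)
  whole <- rect_ring(-1, -1, 8001, 8001)
  sp_nolim <- make_species("a", whole)   # no elevation information
  esh <- compute_esh(sp_nolim, forest, flat, g)
  expect_equal(esh$area, sum(forest) * 1)
  # same range, no forest anywhere
  esh0 <- compute_esh(sp_nolim, matrix(FALSE, 8, 8), flat, g)
  expect_equal(esh0$area, 0)
  # elevation limits bite only when present (inclusive bounds)
  sp_lim <- make_species("b", whole, elev_min = 50, elev_max = 50)
  expect_equal(compute_esh(sp_lim, forest, flat, g)$area, 64)
  sp_out <- make_species("c", whole, elev_min = 60, elev_max = 100)
  expect_equal(compute_esh(sp_out, forest, flat, g)$area, 0)
  # misaligned rasters refuse to combine
  expect_error(compute_esh(sp_nolim, matrix(TRUE, 4, 4), flat, g), "aligned")
})

test_that("habitat change arithmetic and flags", {
  mk <- function(id, area) structure(list(species_id = id, area = area),
                                     class = "esh_result")
  hc <- habitat_change(mk("s", 100), mk("s", 60))
  expect_equal(hc$p_loss, 0.40)
  expect_false(hc$increase)
  expect_equal(habitat_change(mk("s", 100), mk("s", 100))$p_loss, 0)
  up <- habitat_change(mk("s", 100), mk("s", 110))
  expect_equal(up$p_loss, -0.10)
  expect_true(up$increase)
  und <- habitat_change(mk("s", 0), mk("s", 0))
  expect_true(und$undefined)
  expect_true(is.na(und$p_loss))
})

test_that("removing forest never increases ESH; ESH stays inside the range", {
  g <- grid_spec(20, 20, 500)
  sp <- make_species("p", rect_ring(1000, 1000, 8000, 9000))
  flat <- matrix(10, 20, 20)
  set.seed(5)
  for (rep in 1:10) {
    f1 <- matrix(runif(400) < 0.6, 20, 20)
    f2 <- f1 & (matrix(runif(400), 20, 20) < 0.8)  # subset of f1
    a1 <- compute_esh(sp, f1, flat, g)
    a2 <- compute_esh(sp, f2, flat, g)
    expect_lte(a2$area, a1$area)
    expect_true(all(a1$mask <= rasterize_polygon(sp$range, g)))
  }
})

test_that("configured uniform loss is recovered from large ranges", {
  cfg <- synthetic_config(n_rows = 140, n_cols = 140, cell_size = 250,
                          n_islands = 1, island_radius_cells = 60,
                          forest_fraction = 0.85, loss_fraction = 0.2,
                          edge_bias = 0,   # spatially uniform clearing
                          n_species = 0, seed = 13)
  l <- generate_landscape(cfg)
  cs <- l$grid$cell_size
  # a large range in the island interior
  ctr <- which(l$land, arr.ind = TRUE)
  ci <- mean(ctr[, 1]); cj <- mean(ctr[, 2])
  th <- seq(0, 2 * pi, length.out = 25)[-25]
  ring <- cbind((cj + 35 * cos(th)) * cs, (ci + 35 * sin(th)) * cs)
  sp <- make_species("big", ring)
  e0 <- compute_esh(sp, l$forest_t0, l$elevation, l$grid)
  e1 <- compute_esh(sp, l$forest_t1, l$elevation, l$grid)
  expect_gte(sum(e0$mask), 500)
  expect_lte(abs(habitat_change(e0, e1)$p_loss - 0.2), 0.03)
})

test_that("extent of occurrence from hulls of centres and vertices", {
  g <- grid_spec(12, 12, 1000)
  one <- matrix(FALSE, 12, 12); one[3, 4] <- TRUE
  expect_equal(eoo_convex_hull(one, g), 0)   # degenerate point
  expect_error(eoo_convex_hull(matrix(FALSE, 12, 12), g), "empty")

  # right triangle with 10 km legs between cell centres -> 50 km^2
  tri <- matrix(FALSE, 12, 12)
  tri[1, 1] <- TRUE; tri[11, 1] <- TRUE; tri[1, 11] <- TRUE
  shoelace <- function(p) {  # oracle
    n <- nrow(p); s <- 0
    for (k in 1:n) {
      k2 <- if (k == n) 1 else k + 1
      s <- s + p[k, 1] * p[k2, 2] - p[k2, 1] * p[k, 2]
    }
    abs(s) / 2
  }
  pts <- cbind(c(500, 500, 10500), c(500, 10500, 500))
  expect_equal(shoelace(pts) / 1e6, 50)
  expect_equal(eoo_convex_hull(tri, g), 50)

  # a filled 10 x 10 km block: centres span 9 x 9 km
  blk <- matrix(FALSE, 12, 12); blk[1:10, 1:10] <- TRUE
  a <- eoo_convex_hull(blk, g)
  expect_equal(a, 81)
  expect_gte(a, 81); expect_lte(a, 100)
})
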