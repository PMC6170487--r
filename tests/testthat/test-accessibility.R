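test_that("forest edge detection", {
  all_f <- matrix(TRUE, 6, 8)
  e <- forest_edges(all_f)
  ring <- matrix(FALSE, 6, 8)
  ring[c(1, 6), ] <- TRUE; ring[, c(1, 8)] <- TRUE
  expect_identical(e, ring)               # border counts as non-forest
  expect_false(any(forest_edges(matrix(FALSE, 5, 5))))
  single <- matrix(FALSE, 5, 5); single[3, 3] <- TRUE
  expect_identical(forest_edges(single), single)
})

test_that("flat-terrain distances follow the closed form", {
  g <- grid_spec(7, 10, 150)
  forest <- matrix(TRUE, 7, 10)
  flat <- matrix(0, 7, 10)
  src <- matrix(FALSE, 7, 10); src[, 1] <- TRUE
  d <- path_distance(forest, flat, src, g)
  # straight axial path: 5 columns away = 5 * cell_size
  expect_equal(d$distance[4, 6], 5 * 150)
  expect_equal(d$distance[4, 1], 0)
  # diagonal step weight
  g2 <- grid_spec(2, 2, 150)
  s2 <- matrix(FALSE, 2, 2); s2[1, 1] <- TRUE
  d2 <- path_distance(matrix(TRUE, 2, 2), matrix(0, 2, 2), s2, g2)
  expect_equal(d2$distance[2, 2], 150 * sqrt(2))
})

test_that("elevation folds into step length (3-4-5 cells)", {
  g <- grid_spec(1, 2, 150)
  elev <- matrix(c(0, 200), 1, 2)
  src <- matrix(c(TRUE, FALSE), 1, 2)
  d <- path_distance(matrix(TRUE, 1, 2), elev, src, g)
  expect_equal(d$distance[1, 2], 250)  # sqrt(150^2 + 200^2)
})

test_that("lattice distances equal the naive relaxation oracle", {
  set.seed(99)
  for (rep in 1:12) {
    nr <- sample(8:22, 1); nc <- sample(8:22, 1)
    forest <- matrix(runif(nr * nc) < 0.75, nr, nc)
    elev <- matrix(runif(nr * nc, 0, 400), nr, nc)
    src <- forest_edges(forest)
    if (!any(src)) next
    g <- grid_spec(nr, nc, 150)
    d_pkg <- path_distance(forest, elev, src, g)$distance
    d_ora <- relax_path_distance(forest, elev, src, 150)
    expect_equal(d_pkg, d_ora, tolerance = 1e-12)
  }
})

test_that("distance respects flat-terrain lower bound and source monotonicity", {
  set.seed(17)
  nr <- nc <- 20
  forest <- matrix(runif(nr * nc) < 0.8, nr, nc)
  elev <- matrix(runif(nr * nc, 0, 500), nr, nc)
  flat <- matrix(0, nr, nc)
  src <- forest_edges(forest)
  g <- grid_spec(nr, nc, 150)
  d_hill <- path_distance(forest, elev, src, g)$distance
  d_flat <- path_distance(forest, flat, src, g)$distance
  expect_true(all(d_hill >= d_flat - 1e-9))
  # adding sources never increases any distance
  more <- src; more[which(forest)[1]] <- TRUE
  d_more <- path_distance(forest, elev, more, g)$distance
  expect_true(all(d_more <= d_hill + 1e-9))
  # no sources at all: warning and all-Inf surface
  expect_warning(d0 <- path_distance(forest, elev, matrix(FALSE, nr, nc), g),
                 "no source")
  expect_true(all(is.infinite(d0$distance)))
})

test_that("fraction_within counts habitat in reach and is monotone", {
  g <- grid_spec(10, 10, 1000)
  mask <- matrix(FALSE, 10, 10); mask[1:10, 1:10] <- TRUE
  esh <- structure(list(species_id = "s", mask = mask, area = 100),
                   class = "esh_result")
  dmat <- matrix(rep(seq(0, 9000, by = 1000), each = 10), 10, 10)
  dist <- structure(list(grid = g, distance = dmat), class = "distance_raster")
  expect_equal(fraction_within(esh, dist, 1e9)$fraction_within, 1)
  deep <- structure(list(grid = g, distance = dmat + 1e7),
                    class = "distance_raster")
  expect_equal(fraction_within(esh, deep, 5000)$fraction_within, 0)
  expect_equal(fraction_within(esh, dist, 8000)$fraction_within, 0.9)
  expect_equal(fraction_within(esh, dist, 7000)$fraction_within, 0.8)
  fr <- vapply(seq(0, 9000, by = 500),
               function(th) fraction_within(esh, dist, th)$fraction_within,
               numeric(1))
  expect_true(all(diff(fr) >= 0))
  # empty habitat is flagged, not an error
  empty <- structure(list(species_id = "e", mask = matrix(FALSE, 10, 10),
                          area = 0), class = "esh_result")
  expect_true(fraction_within(empty, dist)$empty)
})

test_that("road sources: the major-road subset never reaches more habitat", {
  cfg <- tiny_config(n_species = 6, roads = TRUE, n_roads = 8,
                     n_major_roads = 3, seed = 21)
  l <- generate_landscape(cfg)
  sp <- generate_species(cfg, l)
  expect_error(road_sources(NULL, l$forest_t1), "missing")
  s_all <- road_sources(l$roads, l$forest_t1)
  s_major <- road_sources(l$roads, l$forest_t1, major_only = TRUE,
                          major = l$roads_major)
  expect_true(all(s_major <= s_all))
  d_all <- path_distance(l$forest_t1, l$elevation, s_all, l$grid)
  d_major <- path_distance(l$forest_t1, l$elevation, s_major, l$grid)
  for (s in sp) {
    esh <- compute_esh(s, l$forest_t1, l$elevation, l$grid, date = "t1")
    if (sum(esh$mask) == 0) next
    f_all <- fraction_within(esh, d_all, 5000)$fraction_within
    f_major <- fraction_within(esh, d_major, 5000)$fraction_within
    expect_lte(f_major, f_all)
  }
})
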