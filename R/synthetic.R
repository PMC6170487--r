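# Seeded synthetic landscapes: multi-island equal-area grids with
# edge-biased forest loss, an elevation gradient, a two-country partition,
# protected-area polygons and species ranges of known overlap. Ground
# truth (realized fractions, cleared-cell sets) is exact by construction
# so downstream stages can be tested without external data.

running_mean <- function(x, r) {
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - r, 1)
  hi <- pmin(seq_len(n) + r, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# separable box blur, `passes` times; approximates Gaussian smoothing
blur <- function(m, radius, passes = 3) {
  for (p in seq_len(passes)) {
    m <- apply(m, 2, running_mean, r = radius)
    m <- t(apply(m, 1, running_mean, r = radius))
  }
  m
}

#' Configuration for the synthetic landscape generator
#'
#' Defaults emulate the study system at desk scale: a 200 x 200 grid of
#' 250 m cells (50 x 50 km; the resolution of the land-cover maps the
#' method was built for), three islands, 70% initial forest cover on
#' land, 15% forest loss over a 15-year window concentrated at forest
#' edges, up to ~1500 m of relief, roughly three quarters of the land in
#' the exploitation country, and ~15% of land protected.
#'
#' @param n_rows,n_cols,cell_size,origin grid (see [grid_spec()]).
#' @param n_islands number of island seeds.
#' @param island_radius_cells mean island radius, in cells.
#' @param forest_fraction initial forest fraction of land cells.
#' @param loss_fraction fraction of t0 forest cleared by t1.
#' @param edge_bias non-negative; clearing weight is
#'   `exp(-distance_to_edge * edge_bias / cell_size)`, so larger values
#'   concentrate clearing ever harder at forest edges; 0 means spatially
#'   uniform clearing.
#' @param relief_m maximum elevation.
#' @param country_a_fraction target fraction of land in the exploitation
#'   country (the western part of the grid).
#' @param pa_fraction target protected fraction of land.
#' @param n_species number of species to generate.
#' @param range_radius_cells mean species-range radius, in cells.
#' @param persecution_probs probabilities for none/low/medium/high;
#'   defaults follow the observed 231/29/24/24 split of a 308-species
#'   regional avifauna.
#' @param elev_missing_prob probability a species lacks elevation limits
#'   (default 88/308).
#' @param gen_missing_prob probability generation length is unknown.
#' @param roads generate a road layer.
#' @param n_roads,n_major_roads road counts when `roads`.
#' @param years_between years separating the two forest maps.
#' @param seed integer seed; all generator randomness flows from it.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_rows = 200, n_cols = 200, cell_size = 250,
                             origin = c(0, 0),
                             n_islands = 3, island_radius_cells = 45,
                             forest_fraction = 0.7, loss_fraction = 0.15,
                             edge_bias = 5, relief_m = 1500,
                             country_a_fraction = 0.75, pa_fraction = 0.15,
                             n_species = 40, range_radius_cells = 30,
                             persecution_probs = c(none = 231, low = 29,
                                                   medium = 24, high = 24) / 308,
                             elev_missing_prob = 88 / 308,
                             gen_missing_prob = 0.05,
                             roads = FALSE, n_roads = 6, n_major_roads = 2,
                             years_between = 15, seed = 1L) {
  fracs <- c(forest_fraction, loss_fraction, country_a_fraction, pa_fraction,
             elev_missing_prob, gen_missing_prob)
  if (any(fracs < 0 | fracs > 1))
    stop("all fractions must be in [0, 1]", call. = FALSE)
  stopifnot(edge_bias >= 0, relief_m >= 0, n_species >= 0,
            abs(sum(persecution_probs) - 1) < 1e-8)
  structure(as.list(environment()), class = "synthetic_config")
}

#' Generate a synthetic landscape stack
#'
#' Islands are smoothed random blobs on a sea background (sea cells are
#' non-forest with elevation 0). Initial forest is the most forest-prone
#' fraction of land under a smooth suitability field; clearing between
#' the two dates samples forest cells without replacement with weight
#' `exp(-d_edge * edge_bias / cell_size)`, concentrating loss at forest
#' edges. The realized loss fraction equals the target up to rounding to
#' a whole number of cells.
#'
#' @param config a [synthetic_config()].
#' @return object of class `landscape_stack`.
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  grid <- grid_spec(config$n_rows, config$n_cols, config$cell_size, config$origin)
  nr <- grid$n_rows; nc <- grid$n_cols

  # --- land: Gaussian bumps at island centres + smooth noise ------------
  cc <- cell_centers(grid)
  field <- matrix(0, nr, nc)
  margin <- 0.15
  for (k in seq_len(config$n_islands)) {
    ci <- runif(1, margin, 1 - margin) * nr
    cj <- runif(1, margin, 1 - margin) * nc
    rad <- config$island_radius_cells * runif(1, 0.6, 1.2)
    d2 <- (row(field) - ci)^2 + (col(field) - cj)^2
    field <- field + exp(-d2 / rad^2)
  }
  noise <- blur(matrix(rnorm(nr * nc), nr, nc), radius = max(2, nr %/% 40))
  noise <- (noise - mean(noise)) / stats::sd(noise)
  field <- field + 0.08 * noise
  land <- field > exp(-1)  # bump value at one island radius

  # --- elevation: smooth, highest in island interiors, 0 at sea ---------
  ef <- blur(matrix(rnorm(nr * nc), nr, nc), radius = max(3, nr %/% 25))
  ef <- ef - min(ef)
  ef <- ef / max(ef)
  # weight by the island field so interiors sit higher than coasts
  fw <- (field - min(field)) / (max(field) - min(field))
  elevation <- config$relief_m * (0.6 * fw + 0.4 * ef)
  elevation[!land] <- 0

  # --- initial forest: top fraction of land under a suitability field ---
  n_land <- sum(land)
  forest_t0 <- matrix(FALSE, nr, nc)
  if (n_land > 0 && config$forest_fraction > 0) {
    suit <- blur(matrix(rnorm(nr * nc), nr, nc), radius = max(2, nr %/% 50))
    n_forest <- round(config$forest_fraction * n_land)
    idx <- which(land)
    keep <- idx[order(suit[idx], decreasing = TRUE)[seq_len(n_forest)]]
    forest_t0[keep] <- TRUE
  }

  # --- edge-biased clearing --------------------------------------------
  forest_t1 <- forest_t0
  n_forest <- sum(forest_t0)
  n_loss <- round(config$loss_fraction * n_forest)
  if (n_loss > 0) {
    fidx <- which(forest_t0)
    if (config$edge_bias > 0) {
      edges <- forest_edges(forest_t0)
      d <- cpp_path_distance(forest_t0, matrix(0, nr, nc), edges, grid$cell_size)
      w <- exp(-d[fidx] * config$edge_bias / grid$cell_size)
      w[!is.finite(w)] <- 0
      if (sum(w) <= 0) w <- rep(1, length(fidx))
    } else {
      w <- rep(1, length(fidx))
    }
    cleared <- if (n_loss >= length(fidx)) fidx else sample(fidx, n_loss, prob = w)
    forest_t1[cleared] <- FALSE
  }

  # --- two-country partition: western columns are country A -------------
  country_a <- matrix(FALSE, nr, nc)
  if (n_land > 0 && config$country_a_fraction > 0) {
    land_by_col <- colSums(land)
    cum <- cumsum(land_by_col) / n_land
    cut_col <- which(cum >= config$country_a_fraction)[1]
    if (is.na(cut_col)) cut_col <- nc
    country_a[, seq_len(cut_col)] <- TRUE
  }

  # --- protected areas: rectangles on land, with IUCN categories --------
  pa_polygons <- list()
  protected <- matrix(FALSE, nr, nc)
  if (n_land > 0 && config$pa_fraction > 0) {
    target <- config$pa_fraction * n_land
    land_idx <- which(land)
    tries <- 0
    while (sum(protected & land) < target && tries < 200) {
      tries <- tries + 1
      ctr <- land_idx[sample.int(length(land_idx), 1)]
      ci <- (ctr - 1) %% nr + 1
      cj <- (ctr - 1) %/% nr + 1
      hw <- sample(4:max(5, nc %/% 12), 1)   # half-width in cells
      hh <- sample(4:max(5, nr %/% 12), 1)
      cs <- grid$cell_size
      x0 <- grid$origin[1] + (cj - 1 - hw) * cs
      x1 <- grid$origin[1] + (cj + hw) * cs
      y0 <- grid$origin[2] + (ci - 1 - hh) * cs
      y1 <- grid$origin[2] + (ci + hh) * cs
      category <- sample(c("I", "II", "III", "IV", "V", "VI"), 1,
                         prob = c(0.15, 0.3, 0.1, 0.2, 0.15, 0.1))
      poly <- list(coords = cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1)),
                   properties = list(
                     name = sprintf("PA%02d", length(pa_polygons) + 1L),
                     iucn_category = category))
      pa_polygons[[length(pa_polygons) + 1L]] <- poly
      if (category %in% c("I", "II", "III", "IV", "V"))
        protected <- protected | rasterize_polygon(poly$coords, grid)
    }
  }

  # --- roads: straight lines between random border points ---------------
  roads <- roads_major <- NULL
  if (isTRUE(config$roads) && config$n_roads > 0) {
    roads <- matrix(FALSE, nr, nc)
    roads_major <- matrix(FALSE, nr, nc)
    border_pt <- function() {
      side <- sample(4, 1)
      switch(side,
             c(1, sample(nc, 1)), c(nr, sample(nc, 1)),
             c(sample(nr, 1), 1), c(sample(nr, 1), nc))
    }
    for (k in seq_len(config$n_roads)) {
      a <- border_pt(); b <- border_pt()
      n_step <- max(abs(b - a)) + 1
      ii <- round(seq(a[1], b[1], length.out = n_step))
      jj <- round(seq(a[2], b[2], length.out = n_step))
      roads[cbind(ii, jj)] <- TRUE
      if (k <= config$n_major_roads) roads_major[cbind(ii, jj)] <- TRUE
    }
  }

  structure(list(grid = grid, land = land,
                 forest_t0 = forest_t0, forest_t1 = forest_t1,
                 elevation = elevation, country_a = country_a,
                 protected = protected, pa_polygons = pa_polygons,
                 roads = roads, roads_major = roads_major,
                 years_between = config$years_between,
                 config = config),
            class = "landscape_stack")
}

#' @export
print.landscape_stack <- function(x, ...) {
  g <- x$grid
  cat(sprintf(paste0("<landscape_stack> %d x %d cells of %g m\n",
                     "  land %.1f%% | forest t0 %.1f%% of land | loss %.1f%%",
                     " of forest | protected %.1f%% of land\n"),
              g$n_rows, g$n_cols, g$cell_size,
              100 * mean(x$land),
              100 * sum(x$forest_t0) / max(sum(x$land), 1),
              100 * sum(x$forest_t0 & !x$forest_t1) / max(sum(x$forest_t0), 1),
              100 * sum(x$protected & x$land) / max(sum(x$land), 1)))
  invisible(x)
}

# irregular closed ring around (cx, cy): a circle with low-order harmonic
# perturbation of the radius, so ranges are blob-like but star-convex
blob_ring <- function(cx, cy, radius, n_vertices = 24) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  amp <- runif(3, 0, 0.12)
  ph <- runif(3, 0, 2 * pi)
  r <- radius * (1 + amp[1] * sin(th + ph[1]) + amp[2] * sin(2 * th + ph[2]) +
                   amp[3] * sin(3 * th + ph[3]))
  cbind(cx + r * cos(th), cy + r * sin(th))
}

#' Generate a synthetic species set
#'
#' Each species gets a contiguous blob-shaped range polygon centred on a
#' random land cell, elevation limits (absent with probability
#' `elev_missing_prob`, emulating species with no published elevational
#' range), a generation length, a persecution category, and a
#' forest-dependency flag. Ranges near the grid border may extend past
#' it, producing non-endemic species (range fraction inside the study
#' region < 1). Seeded deterministically from `config$seed` (offset by 1
#' so landscape and species streams are independent).
#'
#' @param config a [synthetic_config()].
#' @param landscape a [generate_landscape()] result.
#' @return list of species records (class `species_record`): `species_id`,
#'   `range` (ring matrix, metres), `elev_min`, `elev_max`,
#'   `generation_length`, `persecution`, `forest_dependent`.
#' @export
generate_species <- function(config, landscape) {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(landscape, "landscape_stack"))
  if (config$n_species == 0) return(list())
  set.seed(config$seed + 1L)
  grid <- landscape$grid
  cs <- grid$cell_size
  cc <- cell_centers(grid)
  land_idx <- which(landscape$land)
  if (length(land_idx) == 0) stop("landscape has no land", call. = FALSE)
  cats <- names(config$persecution_probs)

  out <- vector("list", config$n_species)
  for (k in seq_len(config$n_species)) {
    # rejection-sample a range that covers at least one land cell
    for (try in 1:50) {
      ctr <- land_idx[sample.int(length(land_idx), 1)]
      radius <- cs * config$range_radius_cells *
        exp(rnorm(1, mean = 0, sd = 0.5))
      radius <- max(radius, 1.5 * cs)
      ring <- blob_ring(cc$x[ctr], cc$y[ctr], radius)
      mask <- rasterize_polygon(ring, grid)
      if (any(mask & landscape$land)) break
    }
    if (runif(1) < config$elev_missing_prob) {
      emin <- emax <- NA_real_
    } else {
      ev <- landscape$elevation[mask & landscape$land]
      if (length(ev) == 0) ev <- 0
      emin <- 0
      emax <- max(unname(quantile(ev, runif(1, 0.7, 0.98))), 1)
    }
    gl <- if (runif(1) < config$gen_missing_prob) NA_real_ else
      round(exp(rnorm(1, log(3.8), 0.35)), 1)
    out[[k]] <- structure(list(
      species_id = sprintf("sp%03d", k),
      range = ring,
      elev_min = emin, elev_max = emax,
      generation_length = gl,
      persecution = sample(cats, 1, prob = config$persecution_probs),
      forest_dependent = TRUE), class = "species_record")
  }
  out
}

#' Species trait table
#' @param species list of species records.
#' @return data.frame of the non-geometry traits.
#' @export
species_traits <- function(species) {
  do.call(rbind, lapply(species, function(s) data.frame(
    species_id = s$species_id, elev_min = s$elev_min, elev_max = s$elev_max,
    generation_length = s$generation_length, persecution = s$persecution,
    forest_dependent = s$forest_dependent, stringsAsFactors = FALSE)))
}

#' Fraction of a species' range inside a region mask
#'
#' Rasterized range cells inside the mask times cell area, over the
#' planar polygon area (clamped to 1). Ranges extending past the grid
#' have fractions below 1, emulating non-endemics.
#'
#' @param species species record.
#' @param region logical matrix (e.g. the whole grid, or land).
#' @param grid a [grid_spec()].
#' @return fraction in `[0, 1]`.
#' @export
range_region_fraction <- function(species, region, grid) {
  mask <- rasterize_polygon(species$range, grid)
  a_in <- raster_area_km2(mask & region, grid)
  a_tot <- polygon_area_km2(species$range)
  if (a_tot <= 0) return(NA_real_)
  min(a_in / a_tot, 1)
}

#' Write a landscape stack to a directory
#'
#' Rasters go to ESRI ASCII grids, protected-area polygons to GeoJSON.
#'
#' @param landscape a `landscape_stack`.
#' @param dir output directory (created if needed).
#' @return invisibly `dir`.
#' @export
write_landscape <- function(landscape, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- landscape$grid
  write_ascii_grid(landscape$forest_t0, g, file.path(dir, "forest_t0.asc"))
  write_ascii_grid(landscape$forest_t1, g, file.path(dir, "forest_t1.asc"))
  write_ascii_grid(landscape$elevation, g, file.path(dir, "elevation.asc"))
  write_ascii_grid(landscape$country_a, g, file.path(dir, "country_a.asc"))
  write_ascii_grid(landscape$protected, g, file.path(dir, "protected.asc"))
  write_ascii_grid(landscape$land, g, file.path(dir, "land.asc"))
  if (!is.null(landscape$roads)) {
    write_ascii_grid(landscape$roads, g, file.path(dir, "roads.asc"))
    write_ascii_grid(landscape$roads_major, g, file.path(dir, "roads_major.asc"))
  }
  if (length(landscape$pa_polygons))
    write_geojson(landscape$pa_polygons, file.path(dir, "protected_areas.geojson"))
  jsonlite::write_json(list(years_between = landscape$years_between),
                       file.path(dir, "landscape_meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a landscape stack written by [write_landscape()]
#' @param dir directory.
#' @return a `landscape_stack` (without the generating config).
#' @export
read_landscape <- function(dir) {
  rd <- function(f, logical = FALSE)
    read_ascii_grid(file.path(dir, f), logical = logical)
  f0 <- rd("forest_t0.asc", logical = TRUE)
  meta <- jsonlite::read_json(file.path(dir, "landscape_meta.json"))
  roads_path <- file.path(dir, "roads.asc")
  structure(list(
    grid = f0$grid,
    land = rd("land.asc", logical = TRUE)$values,
    forest_t0 = f0$values,
    forest_t1 = rd("forest_t1.asc", logical = TRUE)$values,
    elevation = rd("elevation.asc")$values,
    country_a = rd("country_a.asc", logical = TRUE)$values,
    protected = rd("protected.asc", logical = TRUE)$values,
    pa_polygons = if (file.exists(file.path(dir, "protected_areas.geojson")))
      read_geojson(file.path(dir, "protected_areas.geojson")) else list(),
    roads = if (file.exists(roads_path)) rd("roads.asc", logical = TRUE)$values,
    roads_major = if (file.exists(roads_path))
      rd("roads_major.asc", logical = TRUE)$values,
    years_between = meta$years_between),
    class = "landscape_stack")
}

#' Write a species set (GeoJSON ranges + CSV traits)
#' @param species list of species records.
#' @param dir output directory.
#' @return invisibly `dir`.
#' @export
write_species_set <- function(species, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  feats <- lapply(species, function(s)
    list(coords = s$range, properties = list(species_id = s$species_id)))
  write_geojson(feats, file.path(dir, "ranges.geojson"))
  write.csv(species_traits(species), file.path(dir, "traits.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' Read a species set written by [write_species_set()]
#' @param dir directory.
#' @return list of species records.
#' @export
read_species_set <- function(dir) {
  feats <- read_geojson(file.path(dir, "ranges.geojson"))
  traits <- read.csv(file.path(dir, "traits.csv"), stringsAsFactors = FALSE)
  geo <- setNames(lapply(feats, `[[`, "coords"),
                  vapply(feats, function(f) f$properties$species_id, character(1)))
  lapply(seq_len(nrow(traits)), function(k) {
    tr <- traits[k, ]
    structure(list(species_id = tr$species_id, range = geo[[tr$species_id]],
                   elev_min = tr$elev_min, elev_max = tr$elev_max,
                   generation_length = tr$generation_length,
                   persecution = tr$persecution,
                   forest_dependent = tr$forest_dependent),
              class = "species_record")
  })
}
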