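# Independent oracles and small fixture builders used across the suite.

# Shift a matrix by (di, dj): out[i, j] = m[i - di, j - dj], `fill` outside.
shift_mat <- function(m, di, dj, fill = Inf) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  src_i <- max(1, 1 - di):min(nr, nr - di)
  src_j <- max(1, 1 - dj):min(nc, nc - dj)
  if (length(src_i) > 0 && length(src_j) > 0)
    out[src_i + di, src_j + dj] <- m[src_i, src_j]
  out
}

# Naive shortest-path oracle: Bellman-Ford style relaxation over the
# 8-connected lattice with octile surface-length weights, iterated to a
# fixed point. Independent of the package's Dijkstra.
relax_path_distance <- function(forest, elevation, sources, cell_size) {
  allowed <- forest | sources
  dist <- matrix(Inf, nrow(forest), ncol(forest))
  dist[sources] <- 0
  moves <- expand.grid(di = -1:1, dj = -1:1)
  moves <- moves[!(moves$di == 0 & moves$dj == 0), ]
  repeat {
    new <- dist
    for (k in seq_len(nrow(moves))) {
      di <- moves$di[k]; dj <- moves$dj[k]
      h <- if (di != 0 && dj != 0) cell_size * sqrt(2) else cell_size
      nd <- shift_mat(dist, di, dj)
      ne <- shift_mat(elevation, di, dj, fill = NA)
      w <- sqrt(h^2 + (elevation - ne)^2)
      cand <- nd + w
      cand[is.na(cand)] <- Inf
      new <- pmin(new, cand)
    }
    new[!allowed] <- Inf
    new[sources] <- 0
    if (all(new == dist | (is.infinite(new) & is.infinite(dist)))) break
    dist <- new
  }
  dist
}

# species record built by hand (bypasses the generator)
make_species <- function(id = "spX", ring, elev_min = NA_real_,
                         elev_max = NA_real_, generation_length = 4,
                         persecution = "none") {
  structure(list(species_id = id, range = ring, elev_min = elev_min,
                 elev_max = elev_max, generation_length = generation_length,
                 persecution = persecution, forest_dependent = TRUE),
            class = "species_record")
}

# axis-aligned rectangle ring in metres
rect_ring <- function(x0, y0, x1, y1) {
  cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
}

# small landscape config for fast tests
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_rows = 60, n_cols = 60, cell_size = 250, n_islands = 1,
         island_radius_cells = 22, n_species = 8, range_radius_cells = 10),
    list(...))
  do.call(synthetic_config, args)
}
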