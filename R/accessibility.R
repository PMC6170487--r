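#' Identify forest-edge cells
#'
#' A forest cell is an edge cell when at least one of its 4-neighbours is
#' non-forest; the raster border counts as non-forest, so forest touching
#' the edge of the study grid is edge.
#'
#' @param forest logical matrix.
#' @return logical matrix, `TRUE` at edge cells only.
#' @export
forest_edges <- function(forest) {
  stopifnot(is.matrix(forest))
  nr <- nrow(forest); nc <- ncol(forest)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- forest
  open <- !pad
  any_open <- open[1:nr, 2:(nc + 1)] | open[3:(nr + 2), 2:(nc + 1)] |
              open[2:(nr + 1), 1:nc] | open[2:(nr + 1), 3:(nc + 2)]
  forest & any_open
}

#' Elevation-aware path distance from source cells
#'
#' Shortest-path distance over the 8-connected lattice, restricted to
#' forest cells plus the sources themselves. Each step costs the surface
#' length `sqrt(h^2 + dz^2)` with `h = cell_size` for axial moves and
#' `cell_size * sqrt(2)` for diagonal moves. This is the desk-scale analog
#' of a GIS path-distance operator: distances measure how far into the
#' forest a trapper must travel from an access point, with elevation
#' change folded into step length.
#'
#' @param forest logical matrix: the traversable medium.
#' @param elevation numeric matrix of metres.
#' @param sources logical matrix of access cells (forest edge or roads);
#'   distance 0 there.
#' @param grid a [grid_spec()].
#' @return object of class `distance_raster`: list with `grid` and
#'   `distance` (metres; `Inf` where unreachable or outside forest).
#' @export
path_distance <- function(forest, elevation, sources, grid) {
  check_aligned(forest, grid, "forest")
  check_aligned(elevation, grid, "elevation")
  check_aligned(sources, grid, "sources")
  if (!any(sources)) {
    warning("no source cells: all distances infinite")
    d <- matrix(Inf, grid$n_rows, grid$n_cols)
  } else {
    d <- cpp_path_distance(forest | sources, elevation, sources, grid$cell_size)
  }
  structure(list(grid = grid, distance = d), class = "distance_raster")
}

#' Fraction of a species' habitat within reach of access points
#'
#' The proportion of ESH cells whose path distance from the nearest source
#' is at most `threshold` metres — the exploitation-exposure term E of the
#' decline model.
#'
#' @param esh an [compute_esh()] result.
#' @param dist a [path_distance()] result on the same grid.
#' @param threshold metres; default 5000 (the median maximum distance
#'   trappers penetrate into forest).
#' @return list with `species_id`, `threshold`, `fraction_within`
#'   (`NA` with `empty` flag when the ESH has no cells).
#' @export
fraction_within <- function(esh, dist, threshold = 5000) {
  stopifnot(inherits(dist, "distance_raster"))
  check_aligned(esh$mask, dist$grid, "esh mask")
  n <- sum(esh$mask)
  if (n == 0) {
    return(list(species_id = esh$species_id, threshold = threshold,
                fraction_within = NA_real_, empty = TRUE))
  }
  list(species_id = esh$species_id, threshold = threshold,
       fraction_within = sum(dist$distance[esh$mask] <= threshold) / n,
       empty = FALSE)
}

#' Build path-distance sources from a road layer
#'
#' @param roads logical matrix of road cells; when `major_only`, a second
#'   logical matrix `major` marks the major-road subset.
#' @param forest logical matrix (unused for the source set itself; kept so
#'   the call site mirrors [forest_edges()] usage).
#' @param major_only restrict sources to major roads.
#' @param major logical matrix marking major roads (required when
#'   `major_only`).
#' @return logical matrix of source cells.
#' @export
road_sources <- function(roads, forest, major_only = FALSE, major = NULL) {
  if (is.null(roads)) stop("roads layer is missing", call. = FALSE)
  if (major_only) {
    if (is.null(major)) stop("major-road mask required when major_only", call. = FALSE)
    roads & major
  } else {
    roads
  }
}
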