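#' Rasterize a polygon by the cell-centre rule
#'
#' A cell belongs to the polygon when its centre falls inside or on the
#' boundary of the (single, unclosed) ring. Only cells in the polygon's
#' bounding box are tested.
#'
#' @param coords two-column x,y matrix of ring vertices (metres, unclosed).
#' @param grid a [grid_spec()].
#' @return logical matrix aligned to `grid`.
#' @export
rasterize_polygon <- function(coords, grid) {
  stopifnot(is.matrix(coords), ncol(coords) == 2, nrow(coords) >= 3)
  out <- matrix(FALSE, grid$n_rows, grid$n_cols)
  cs <- grid$cell_size
  # candidate rows/cols from the bounding box
  jr <- floor((range(coords[, 1]) - grid$origin[1]) / cs) + c(0L, 1L)
  ir <- floor((range(coords[, 2]) - grid$origin[2]) / cs) + c(0L, 1L)
  js <- max(1L, jr[1]):min(grid$n_cols, jr[2])
  is <- max(1L, ir[1]):min(grid$n_rows, ir[2])
  if (length(js) == 0 || length(is) == 0) return(out)
  cx <- grid$origin[1] + (js - 0.5) * cs
  cy <- grid$origin[2] + (is - 0.5) * cs
  px <- rep(cx, each = length(is))
  py <- rep(cy, times = length(js))
  inside <- sp::point.in.polygon(px, py, coords[, 1], coords[, 2]) > 0
  out[cbind(rep(is, times = length(js)), rep(js, each = length(is)))] <- inside
  out
}

#' Planar polygon area (shoelace), in square kilometres
#' @param coords two-column x,y matrix of ring vertices in metres, unclosed.
#' @return area in km^2.
#' @export
polygon_area_km2 <- function(coords) {
  x <- coords[, 1]; y <- coords[, 2]
  n <- nrow(coords)
  xn <- x[c(2:n, 1)]; yn <- y[c(2:n, 1)]
  abs(sum(x * yn - xn * y)) / 2 / 1e6
}

#' Extent of suitable habitat for one species at one date
#'
#' ESH = rasterized range  AND  forest  AND (when the species has
#' elevation limits) `elev_min <= elevation <= elev_max` (inclusive
#' bounds). Species with no recorded elevation limits skip the elevation
#' clip.
#'
#' @param species a species record (see [generate_species()]): needs
#'   `species_id`, `range` (ring matrix), and optionally `elev_min`,
#'   `elev_max`.
#' @param forest logical matrix for the date of interest.
#' @param elevation numeric matrix of metres.
#' @param grid a [grid_spec()].
#' @param date label stored on the result (e.g. `"t0"`).
#' @return object of class `esh_result`: `species_id`, `date`, `mask`
#'   (logical matrix), `area` (km^2).
#' @export
compute_esh <- function(species, forest, elevation, grid, date = "t0") {
  check_aligned(forest, grid, "forest")
  check_aligned(elevation, grid, "elevation")
  range_mask <- rasterize_polygon(species$range, grid)
  if (!any(range_mask))
    warning(sprintf("species %s: rasterized range is empty", species$species_id))
  mask <- range_mask & forest
  if (!is.null(species$elev_min) && !is.na(species$elev_min) &&
      !is.null(species$elev_max) && !is.na(species$elev_max)) {
    mask <- mask & (elevation >= species$elev_min) & (elevation <= species$elev_max)
  }
  structure(list(species_id = species$species_id, date = date, mask = mask,
                 area = raster_area_km2(mask, grid)),
            class = "esh_result")
}

#' Habitat change between two dates
#'
#' `p_loss` is the proportion of the time-0 ESH lost by time 1 (the p term
#' of the annual-rate model). Habitat increases give a negative `p_loss`
#' and set the `increase` flag; a zero time-0 area makes `p_loss`
#' undefined (`NA`) and sets `undefined` so the species is excluded from
#' decline-based listing.
#'
#' @param esh_t0,esh_t1 [compute_esh()] results for the same species.
#' @return list: `species_id`, `area_t0`, `area_t1`, `p_loss`, flags
#'   `increase` and `undefined`.
#' @export
habitat_change <- function(esh_t0, esh_t1) {
  stopifnot(esh_t0$species_id == esh_t1$species_id)
  a0 <- esh_t0$area; a1 <- esh_t1$area
  if (a0 <= 0) {
    return(list(species_id = esh_t0$species_id, area_t0 = a0, area_t1 = a1,
                p_loss = NA_real_, increase = FALSE, undefined = TRUE))
  }
  p <- (a0 - a1) / a0
  list(species_id = esh_t0$species_id, area_t0 = a0, area_t1 = a1,
       p_loss = p, increase = p < 0, undefined = FALSE)
}

#' Extent of occurrence: minimum convex polygon area
#'
#' Area (km^2) of the convex hull of either the occupied cell centres of a
#' mask or the vertices of a range polygon. Degenerate inputs (a single
#' point, collinear points) have zero hull area.
#'
#' @param x logical matrix (occupied-cell mask) or two-column coordinate
#'   matrix in metres.
#' @param grid a [grid_spec()]; required when `x` is a mask.
#' @return hull area in km^2.
#' @export
eoo_convex_hull <- function(x, grid = NULL) {
  if (is.logical(x) && is.matrix(x)) {
    stopifnot(!is.null(grid))
    if (!any(x)) stop("empty mask: extent of occurrence undefined", call. = FALSE)
    cc <- cell_centers(grid)
    pts <- cbind(cc$x[x], cc$y[x])
  } else {
    pts <- x
    stopifnot(is.matrix(pts), ncol(pts) == 2)
    if (nrow(pts) == 0) stop("no vertices: extent of occurrence undefined", call. = FALSE)
  }
  pts <- unique(pts)
  if (nrow(pts) < 3) return(0)
  h <- chull(pts)
  polygon_area_km2(pts[h, , drop = FALSE])
}
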