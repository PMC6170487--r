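#' Define an equal-area raster grid
#'
#' All rasters in a landscape share one grid: square cells of side
#' `cell_size` metres in an equal-area projection, `n_rows` x `n_cols`,
#' anchored at `origin` (the outer corner of cell \[1,1\]). Cell \[i,j\]
#' (1-based) has its centre at `origin + (j - 0.5, i - 0.5) * cell_size`,
#' so the row index increases with the y ("northing") coordinate.
#'
#' @param n_rows,n_cols grid dimensions (positive integers).
#' @param cell_size cell edge length in metres.
#' @param origin numeric length-2, (x, y) of the grid corner in metres.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows, n_cols, cell_size, origin = c(0, 0)) {
  stopifnot(n_rows >= 1, n_cols >= 1, cell_size > 0, length(origin) == 2)
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         cell_size = as.numeric(cell_size), origin = as.numeric(origin)),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells of %g m (%.1f x %.1f km)\n",
              x$n_rows, x$n_cols, x$cell_size,
              x$n_cols * x$cell_size / 1000, x$n_rows * x$cell_size / 1000))
  invisible(x)
}

#' Cell area of a grid in square kilometres
#' @param grid a [grid_spec()].
#' @return scalar km^2 per cell.
#' @export
cell_area_km2 <- function(grid) (grid$cell_size / 1000)^2

#' Cell-centre coordinates
#'
#' @param grid a [grid_spec()].
#' @return list with matrices `x` and `y` (n_rows x n_cols) of centre
#'   coordinates in metres.
#' @export
cell_centers <- function(grid) {
  xs <- grid$origin[1] + (seq_len(grid$n_cols) - 0.5) * grid$cell_size
  ys <- grid$origin[2] + (seq_len(grid$n_rows) - 0.5) * grid$cell_size
  list(x = matrix(xs, grid$n_rows, grid$n_cols, byrow = TRUE),
       y = matrix(ys, grid$n_rows, grid$n_cols))
}

#' Check that a raster matrix conforms to a grid
#' @param r matrix.
#' @param grid a [grid_spec()].
#' @param what label used in error messages.
#' @return invisibly `r`; errors if dimensions disagree.
#' @export
check_aligned <- function(r, grid, what = "raster") {
  if (!is.matrix(r) || nrow(r) != grid$n_rows || ncol(r) != grid$n_cols)
    stop(sprintf("%s is not aligned to the grid (%d x %d expected, got %s)",
                 what, grid$n_rows, grid$n_cols,
                 paste(dim(r), collapse = " x ")), call. = FALSE)
  invisible(r)
}

raster_area_km2 <- function(mask, grid) sum(mask) * cell_area_km2(grid)
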