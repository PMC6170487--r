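#' Write a raster matrix as an ESRI ASCII grid
#'
#' Plain-text interchange format readable by any GIS. Logical rasters are
#' written as 0/1. Rows are written north-to-south (the file's first data
#' row is the matrix row with the largest y).
#'
#' @param r matrix (numeric or logical) aligned to `grid`.
#' @param grid a [grid_spec()].
#' @param path output file path.
#' @param nodata value standing in for `NA`/non-finite cells.
#' @return invisibly `path`.
#' @export
write_ascii_grid <- function(r, grid, path, nodata = -9999) {
  check_aligned(r, grid)
  m <- r
  if (is.logical(m)) m <- m * 1L
  m[!is.finite(m)] <- nodata
  hdr <- c(
    sprintf("ncols %d", grid$n_cols),
    sprintf("nrows %d", grid$n_rows),
    sprintf("xllcorner %.10g", grid$origin[1]),
    sprintf("yllcorner %.10g", grid$origin[2]),
    sprintf("cellsize %.10g", grid$cell_size),
    sprintf("NODATA_value %.10g", nodata))
  body <- apply(m[grid$n_rows:1, , drop = FALSE], 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path file written by [write_ascii_grid()] (or any conforming .asc).
#' @param logical interpret the layer as a 0/1 mask and return a logical
#'   matrix.
#' @return list with `grid` (a [grid_spec()]) and `values` (matrix; NODATA
#'   cells become `NA`).
#' @export
read_ascii_grid <- function(path, logical = FALSE) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  val <- function(key) {
    ln <- hdr[grepl(paste0("^", key, "\\b"), hdr, ignore.case = TRUE)]
    as.numeric(strsplit(trimws(ln), "\\s+")[[1]][2])
  }
  nc <- val("ncols"); nr <- val("nrows")
  grid <- grid_spec(nr, nc, val("cellsize"), c(val("xllcorner"), val("yllcorner")))
  nodata <- val("NODATA_value")
  m <- matrix(scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE),
              nrow = nr, ncol = nc, byrow = TRUE)
  m <- m[nr:1, , drop = FALSE]   # back to row index = increasing y
  m[m == nodata] <- NA
  if (logical) m <- m > 0
  list(grid = grid, values = m)
}

#' Write polygon features as GeoJSON
#'
#' @param polys list of features; each feature is a list with `coords`
#'   (two-column x,y matrix, unclosed ring) and optionally a named list
#'   `properties`.
#' @param path output file path.
#' @return invisibly `path`.
#' @export
write_geojson <- function(polys, path) {
  feats <- lapply(polys, function(p) {
    ring <- rbind(p$coords, p$coords[1, , drop = FALSE])
    list(
      type = "Feature",
      properties = if (is.null(p$properties)) structure(list(), names = character())
                   else p$properties,
      geometry = list(
        type = "Polygon",
        coordinates = list(lapply(seq_len(nrow(ring)),
                                  function(k) unname(ring[k, ])))))
  })
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}

#' Read polygon features from GeoJSON
#'
#' Only Polygon geometries (outer ring) are consumed; holes and multipart
#' geometries are not supported by this package's generators.
#'
#' @param path GeoJSON file.
#' @return list of features in the format accepted by [write_geojson()].
#' @export
read_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  lapply(fc$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
    # drop the closing vertex
    if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
    list(coords = m, properties = f$properties)
  })
}
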