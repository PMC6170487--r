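#' Protected-area coverage of a species' habitat
#'
#' @param esh [compute_esh()] result (current-date ESH).
#' @param protected logical matrix: the protected-area mask (IUCN
#'   categories I-V, filtered at mask-build time).
#' @param grid a [grid_spec()].
#' @return list: `species_id`, `area_km2` (ESH inside PAs), `fraction`
#'   (of the ESH; `NA` with `empty` flag when the ESH has no cells).
#' @export
pa_coverage <- function(esh, protected, grid) {
  check_aligned(esh$mask, grid, "esh mask")
  check_aligned(protected, grid, "protected")
  n <- sum(esh$mask)
  inside <- esh$mask & protected
  list(species_id = esh$species_id,
       area_km2 = raster_area_km2(inside, grid),
       fraction = if (n == 0) NA_real_ else sum(inside) / n,
       empty = n == 0)
}

#' Hunting-safe core protected coverage
#'
#' Protected habitat beyond the trapper-penetration threshold from the
#' forest edge: ESH AND PA AND (path distance > threshold). At threshold 0
#' this equals [pa_coverage()].
#'
#' @param esh [compute_esh()] result.
#' @param protected logical PA mask.
#' @param dist [path_distance()] result (forest-edge sources).
#' @param grid a [grid_spec()].
#' @param threshold metres, default 5000.
#' @return list as [pa_coverage()] with `threshold` added.
#' @export
core_pa_coverage <- function(esh, protected, dist, grid, threshold = 5000) {
  check_aligned(esh$mask, grid, "esh mask")
  check_aligned(protected, grid, "protected")
  check_aligned(dist$distance, grid, "distance")
  n <- sum(esh$mask)
  core <- esh$mask & protected & (dist$distance > threshold)
  list(species_id = esh$species_id, threshold = threshold,
       area_km2 = raster_area_km2(core, grid),
       fraction = if (n == 0) NA_real_ else sum(core) / n,
       empty = n == 0)
}

#' Per-species protection assessment
#'
#' Combines plain and core PA coverage and sets the area-threshold flags.
#' Following the convention that exploitation reaches inside protected
#' areas, the Vulnerable (2000 km^2, flag set when area <= threshold) and
#' Critically Endangered (10 km^2, flag set when area < threshold) checks
#' are applied to the hunting-safe core area; the plain coverage is
#' reported alongside so the alternative reading is computable.
#'
#' @param esh [compute_esh()] result.
#' @param protected logical PA mask.
#' @param dist [path_distance()] result.
#' @param grid a [grid_spec()].
#' @param threshold metres, default 5000.
#' @param vu_km2,cr_km2 area thresholds, defaults 2000 and 10.
#' @return list of class `protection_result`.
#' @export
protection_assess <- function(esh, protected, dist, grid, threshold = 5000,
                              vu_km2 = 2000, cr_km2 = 10) {
  pa <- pa_coverage(esh, protected, grid)
  core <- core_pa_coverage(esh, protected, dist, grid, threshold)
  structure(list(
    species_id = esh$species_id,
    esh_km2 = esh$area,
    esh_in_pa_km2 = pa$area_km2, fraction_in_pa = pa$fraction,
    core_in_pa_km2 = core$area_km2, fraction_core_in_pa = core$fraction,
    below_vu_threshold = core$area_km2 <= vu_km2,
    below_cr_threshold = core$area_km2 < cr_km2),
    class = "protection_result")
}
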