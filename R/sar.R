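#' Species-area extinction fraction
#'
#' Ratio form of the power-law species-area relationship `S = c A^z` with
#' `c = 1`: when habitat shrinks to `habitat_ratio` of its original area,
#' the fraction of species eventually lost is `1 - habitat_ratio^z`.
#'
#' @param habitat_ratio future area / original area, in `[0, 1]`.
#' @param z species-area exponent (> 0); 0.18-0.35 spans published values
#'   for tropical forest biota.
#' @return extinction fraction in `[0, 1]`.
#' @export
extinction_fraction <- function(habitat_ratio, z) {
  stopifnot(all(habitat_ratio >= 0 & habitat_ratio <= 1), all(z > 0))
  1 - habitat_ratio^z
}

#' Invert the species-area relationship
#'
#' The habitat ratio implying a given extinction fraction:
#' `(1 - fraction)^(1/z)`. Round-trips with [extinction_fraction()] to
#' machine precision.
#'
#' @param fraction extinction fraction in `[0, 1)`.
#' @param z species-area exponent.
#' @return habitat ratio in `(0, 1]`.
#' @export
invert_habitat_ratio <- function(fraction, z) {
  stopifnot(all(z > 0))
  if (any(fraction < 0 | fraction >= 1))
    stop("extinction fraction must be in [0, 1)", call. = FALSE)
  (1 - fraction)^(1 / z)
}

#' Project forest area forward at a constant annual loss rate
#'
#' @param forest_area_t0 area at the start (any unit).
#' @param annual_rate proportional loss per year in `[0, 1)`.
#' @param years years elapsed.
#' @return projected area, `forest_area_t0 * (1 - annual_rate)^years`.
#' @export
project_forest_to <- function(forest_area_t0, annual_rate, years) {
  stopifnot(all(annual_rate >= 0 & annual_rate < 1), years >= 0)
  forest_area_t0 * (1 - annual_rate)^years
}

#' Species-area extinction projection table
#'
#' For each exponent `z`, the extinction fraction implied by a habitat
#' ratio (given directly, or projected from an area and annual loss rate)
#' and the corresponding species count out of `species_pool` (truncated
#' toward zero, matching the convention of pairing percentages with
#' counts).
#'
#' @param z_values vector of exponents.
#' @param species_pool species richness of the region.
#' @param habitat_ratio future/original habitat ratio; or supply
#'   `area_t0`, `annual_rate`, `years` to project it.
#' @param area_t0,annual_rate,years alternative projection inputs.
#' @param count_mode `"truncate"` (default) or `"round"`.
#' @return data.frame: `z`, `habitat_ratio`, `extinct_fraction`,
#'   `extinct_percent`, `extinct_species`.
#' @export
sar_table <- function(z_values, species_pool, habitat_ratio = NULL,
                      area_t0 = NULL, annual_rate = NULL, years = NULL,
                      count_mode = c("truncate", "round")) {
  count_mode <- match.arg(count_mode)
  if (is.null(habitat_ratio)) {
    stopifnot(!is.null(area_t0), !is.null(annual_rate), !is.null(years))
    habitat_ratio <- project_forest_to(area_t0, annual_rate, years) / area_t0
  }
  frac <- extinction_fraction(habitat_ratio, z_values)
  n <- frac * species_pool
  n <- if (count_mode == "truncate") trunc(n) else round(n)
  data.frame(z = z_values, habitat_ratio = habitat_ratio,
             extinct_fraction = frac, extinct_percent = frac * 100,
             extinct_species = as.integer(n))
}
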