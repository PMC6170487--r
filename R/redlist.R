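RL_LEVELS <- c("LC", "NT", "VU", "EN", "CR")

rl_severity <- function(cat) match(cat, RL_LEVELS)

rl_max <- function(a, b) {
  if (is.na(b) || !nzchar(b)) return(a)
  if (is.na(a) || !nzchar(a)) return(b)
  RL_LEVELS[max(rl_severity(a), rl_severity(b))]
}

#' Red List assessment window
#'
#' Three generations or 10 years, whichever is longer. A missing
#' generation length falls back to 10 years with a warning.
#'
#' @param generation_length years, or `NA`/`NULL`.
#' @return window in years.
#' @export
assessment_window <- function(generation_length) {
  if (is.null(generation_length) || is.na(generation_length)) {
    warning("generation length unknown: using the 10-year floor")
    return(10)
  }
  if (generation_length <= 0) stop("generation length must be positive", call. = FALSE)
  max(3 * generation_length, 10)
}

#' Project habitat-driven population decline over the assessment window
#'
#' The observed proportional loss is converted to an annual rate
#' `r = p_loss / observed_years` (floored at 0 when habitat increased) and
#' compounded: `decline = 1 - (1 - r)^window_years`, assuming loss
#' continues at the observed rate and population decline is proportional
#' to habitat decline.
#'
#' @param p_loss observed proportional ESH loss (may be negative).
#' @param observed_years length of the observation window (default 15).
#' @param window_years assessment window from [assessment_window()].
#' @return list: `r_annual`, `window_years`, `decline_deforestation`,
#'   flags `increase` and `rate_capped`.
#' @export
project_decline <- function(p_loss, observed_years = 15, window_years) {
  stopifnot(observed_years > 0, window_years > 0)
  if (is.na(p_loss)) {
    return(list(r_annual = NA_real_, window_years = window_years,
                decline_deforestation = NA_real_,
                increase = FALSE, rate_capped = FALSE))
  }
  increase <- p_loss < 0
  r <- max(p_loss, 0) / observed_years
  capped <- r >= 1
  decline <- if (capped) 1 else 1 - (1 - r)^window_years
  list(r_annual = r, window_years = window_years,
       decline_deforestation = decline, increase = increase,
       rate_capped = capped)
}

#' Red List category from a projected population decline (criterion A)
#'
#' Inclusive thresholds: CR at >= 80% decline, EN at 50%, VU at 30%, NT at
#' 15% by default (configurable; 20% is the other published convention).
#'
#' @param decline_total fraction >= 0; values above 1 are treated as 1.
#' @param nt_threshold NT threshold as a fraction, default 0.15.
#' @return one of `"LC" "NT" "VU" "EN" "CR"`.
#' @export
classify_decline <- function(decline_total, nt_threshold = 0.15) {
  stopifnot(all(decline_total >= 0, na.rm = TRUE))
  d <- pmin(decline_total, 1)
  out <- ifelse(d >= 0.80, "CR",
         ifelse(d >= 0.50, "EN",
         ifelse(d >= 0.30, "VU",
         ifelse(d >= nt_threshold, "NT", "LC"))))
  out[is.na(d)] <- NA_character_
  out
}

#' Red List category from extent of occurrence (criterion B2 area rule)
#'
#' EN below 500 km^2, VU below 2000 km^2, otherwise no listing from this
#' criterion (strict inequalities).
#'
#' @param eoo_km2 extent of occurrence in km^2.
#' @return `"EN"`, `"VU"` or `NA_character_`.
#' @export
classify_eoo <- function(eoo_km2) {
  stopifnot(all(eoo_km2 >= 0, na.rm = TRUE))
  ifelse(is.na(eoo_km2), NA_character_,
         ifelse(eoo_km2 < 500, "EN", ifelse(eoo_km2 < 2000, "VU", NA_character_)))
}

#' Assess a species cohort
#'
#' Combines per-species habitat change, exploitation estimates, and
#' extent-of-occurrence into Red List assessments. Deforestation and
#' exploitation declines are additive; totals above 1 are capped at 1 for
#' classification (raw totals are reported alongside). The final category
#' is the most severe of criterion A (decline) and criterion B2 (EOO);
#' species routed to the EOO-only pathway (e.g. no-data voids in the
#' habitat maps) skip criterion A. Listing recommendations are made only
#' for regional endemics (range fraction in the study region at or above
#' `endemic_threshold`).
#'
#' @param species list of species records.
#' @param changes named list of [habitat_change()] results keyed by
#'   species id.
#' @param exploitation named list of [exploitation_estimate()] results
#'   keyed by species id (missing entries mean no exploitation).
#' @param region_fraction named numeric: fraction of each species' range
#'   inside the study region.
#' @param eoo named numeric of EOO km^2 (optional per species).
#' @param eoo_routed character vector of species ids assessed by EOO only.
#' @param observed_years years between the two forest maps, default 15.
#' @param nt_threshold see [classify_decline()].
#' @param endemic_threshold default 0.8.
#' @return data.frame, one row per species, plus attribute `"skipped"`
#'   listing species dropped for missing inputs.
#' @export
assess <- function(species, changes, exploitation, region_fraction,
                   eoo = NULL, eoo_routed = character(),
                   observed_years = 15, nt_threshold = 0.15,
                   endemic_threshold = 0.8) {
  rows <- list(); skipped <- character()
  for (sp in species) {
    id <- sp$species_id
    ch <- changes[[id]]
    if (is.null(ch) && !(id %in% eoo_routed)) { skipped <- c(skipped, id); next }
    ex <- exploitation[[id]]
    d_ex_pt <- if (is.null(ex)) 0 else ex$decline_point
    d_ex_lo <- if (is.null(ex)) 0 else ex$decline_lo
    d_ex_hi <- if (is.null(ex)) 0 else ex$decline_hi

    if (id %in% eoo_routed || is.null(ch) || isTRUE(ch$undefined)) {
      d_def <- NA_real_; increase <- FALSE
      total <- total_lo <- total_hi <- NA_real_
      cat_a <- NA_character_
    } else {
      window <- suppressWarnings(assessment_window(sp$generation_length))
      pr <- project_decline(ch$p_loss, observed_years, window)
      d_def <- pr$decline_deforestation
      increase <- pr$increase
      total <- d_def + d_ex_pt
      total_lo <- d_def + d_ex_lo
      total_hi <- d_def + d_ex_hi
      cat_a <- classify_decline(min(total, 1), nt_threshold)
    }
    eoo_i <- if (!is.null(eoo) && !is.null(eoo[[id]])) eoo[[id]] else NA_real_
    cat_b2 <- if (is.na(eoo_i)) NA_character_ else classify_eoo(eoo_i)
    final <- rl_max(if (is.na(cat_a)) "LC" else cat_a, cat_b2)
    driver <- if (is.na(d_def) || (d_ex_pt == 0 && d_def == 0)) NA_character_
              else if (d_ex_pt > d_def) "exploitation" else "deforestation"
    frac_reg <- if (!is.null(region_fraction[[id]])) region_fraction[[id]] else NA_real_
    endemic <- !is.na(frac_reg) && frac_reg >= endemic_threshold
    rows[[id]] <- data.frame(
      species_id = id, persecution = sp$persecution,
      decline_deforestation = d_def,
      decline_exploitation = d_ex_pt,
      decline_total_raw = total,
      decline_total = pmin(total, 1),
      decline_lo = pmin(total_lo, 1), decline_hi = pmin(total_hi, 1),
      category_A = cat_a, eoo_km2 = eoo_i, category_B2 = cat_b2,
      final_category = final,
      primary_driver = driver,
      region_fraction = frac_reg, endemic = endemic,
      recommended = endemic,   # recommendations suppressed for non-endemics
      increase = increase,
      eoo_only = id %in% eoo_routed,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Summarize an assessment table
#'
#' Category counts (among species with recommendations), the threatened
#' total (VU + EN + CR), the percent increase over a baseline threatened
#' count, mean declines by category, and counts of species whose leading
#' decline driver is exploitation.
#'
#' @param assessment data.frame from [assess()] (or any table with the
#'   same columns).
#' @param baseline_threatened previously listed threatened count to
#'   compare against, or `NULL`.
#' @return list of summary components.
#' @export
threat_summary <- function(assessment, baseline_threatened = NULL) {
  rec <- assessment[assessment$recommended, , drop = FALSE]
  counts <- vapply(RL_LEVELS, function(l) sum(rec$final_category == l, na.rm = TRUE),
                   integer(1))
  threatened <- sum(counts[c("VU", "EN", "CR")])
  mean_decl <- vapply(RL_LEVELS, function(l) {
    v <- rec$decline_total[rec$final_category == l]
    if (length(v) == 0) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  drv <- assessment[!is.na(assessment$primary_driver) &
                    assessment$persecution != "none", , drop = FALSE]
  out <- list(
    n_assessed = nrow(assessment),
    n_recommended = nrow(rec),
    category_counts = as.list(counts),
    threatened = threatened,
    mean_decline_by_category = as.list(mean_decl),
    n_exploited = nrow(drv),
    exploitation_dominant = sum(drv$primary_driver == "exploitation"))
  if (!is.null(baseline_threatened)) {
    out$baseline_threatened <- baseline_threatened
    out$percent_increase <- percent_increase(threatened, baseline_threatened)
  }
  out
}

#' Percent increase, rounded to the nearest whole percent
#' @param new,old counts; `old` must be positive.
#' @return percentage (e.g. 89 for 27 -> 51).
#' @export
percent_increase <- function(new, old) {
  stopifnot(old > 0)
  round((new - old) / old * 100)
}
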