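#' Normalize a run configuration
#'
#' Accepts a YAML file path or a list; fills defaults. Sections:
#' `synthetic` (arguments of [synthetic_config()]), `thresholds`
#' (`access_m`, `nt`, `endemic`, `eoo_en_km2`, `eoo_vu_km2`, `pa_vu_km2`,
#' `pa_cr_km2`, `nodata_route`), `efficacy` (per-category
#' min/mode/max/shape overriding [default_efficacy_model()]),
#' `source_mode` (`forest_edge`, `roads_major`, `roads_all`),
#' `exploitation_enabled`, `sar` (`z`, `horizon_years`), `seed`.
#'
#' @param config path to a YAML file, or a list.
#' @return normalized list of class `run_config`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  def <- list(
    seed = 1L,
    synthetic = list(),
    source_mode = "forest_edge",
    exploitation_enabled = TRUE,
    thresholds = list(access_m = 5000, nt = 0.15, endemic = 0.8,
                      eoo_en_km2 = 500, eoo_vu_km2 = 2000,
                      pa_vu_km2 = 2000, pa_cr_km2 = 10, nodata_route = 0.5),
    efficacy = NULL,
    sar = list(z = c(0.18, 0.35), horizon_years = 85))
  out <- utils::modifyList(def, config)
  out$thresholds <- utils::modifyList(def$thresholds, out$thresholds)
  out$sar <- utils::modifyList(def$sar, out$sar)
  if (!out$source_mode %in% c("forest_edge", "roads_major", "roads_all"))
    stop("unknown source_mode: ", out$source_mode, call. = FALSE)
  if (any(unlist(out$thresholds) <= 0)) stop("thresholds must be positive",
                                             call. = FALSE)
  out$synthetic$seed <- out$seed
  structure(out, class = "run_config")
}

efficacy_model_from_config <- function(config) {
  if (is.null(config$efficacy)) return(default_efficacy_model())
  lapply(config$efficacy, function(p)
    pert_params(p$minimum, p$mode, p$maximum,
                if (is.null(p$shape)) 4 else p$shape))
}

access_sources <- function(landscape, source_mode) {
  switch(source_mode,
    forest_edge = forest_edges(landscape$forest_t1),
    roads_major = road_sources(landscape$roads, landscape$forest_t1,
                               major_only = TRUE, major = landscape$roads_major),
    roads_all = road_sources(landscape$roads, landscape$forest_t1))
}

#' Run the full assessment pipeline on a synthetic landscape
#'
#' simulate -> habitat -> accessibility -> exploitation -> Red List ->
#' protection -> species-area projection, writing per-stage CSVs, a
#' summary JSON and a provenance record to `out_dir`. Identical config
#' and seed give identical outputs.
#'
#' @param config a [run_config()] (or anything it accepts).
#' @param out_dir output directory; `NULL` computes everything in memory
#'   and writes nothing.
#' @return invisibly, a list with all stage results (`landscape`,
#'   `species`, `habitat`, `access`, `exploitation`, `assessment`,
#'   `summary`, `protection`, `sar`).
#' @export
run_assessment <- function(config = list(), out_dir = NULL) {
  config <- run_config(if (inherits(config, "run_config")) unclass(config) else config)
  th <- config$thresholds

  sc <- do.call(synthetic_config, config$synthetic)
  landscape <- generate_landscape(sc)
  species <- generate_species(sc, landscape)
  grid <- landscape$grid

  # habitat stage
  esh0 <- lapply(species, compute_esh, forest = landscape$forest_t0,
                 elevation = landscape$elevation, grid = grid, date = "t0")
  esh1 <- lapply(species, compute_esh, forest = landscape$forest_t1,
                 elevation = landscape$elevation, grid = grid, date = "t1")
  ids <- vapply(species, `[[`, character(1), "species_id")
  names(esh0) <- names(esh1) <- ids
  changes <- setNames(Map(habitat_change, esh0, esh1), ids)
  habitat_df <- do.call(rbind, lapply(changes, function(ch) data.frame(
    species_id = ch$species_id, area_t0 = ch$area_t0, area_t1 = ch$area_t1,
    p_loss = ch$p_loss, increase = ch$increase, undefined = ch$undefined,
    stringsAsFactors = FALSE)))
  rownames(habitat_df) <- NULL

  # accessibility stage
  sources <- access_sources(landscape, config$source_mode)
  dist <- path_distance(landscape$forest_t1, landscape$elevation, sources, grid)
  access <- lapply(esh1, fraction_within, dist = dist, threshold = th$access_m)
  access_df <- do.call(rbind, lapply(access, function(a) data.frame(
    species_id = a$species_id, threshold_m = a$threshold,
    fraction_within = a$fraction_within, source_mode = config$source_mode,
    stringsAsFactors = FALSE)))
  rownames(access_df) <- NULL

  # exploitation stage
  model <- efficacy_model_from_config(config)
  exploitation <- setNames(vector("list", length(species)), ids)
  for (k in seq_along(species)) {
    sp <- species[[k]]; id <- ids[k]
    n1 <- sum(esh1[[id]]$mask)
    p_country <- if (n1 == 0) 0 else
      sum(esh1[[id]]$mask & landscape$country_a) / n1
    e_within <- if (isTRUE(access[[id]]$empty)) 0 else access[[id]]$fraction_within
    if (!config$exploitation_enabled) {
      sp <- sp; sp$persecution <- "none"
    }
    exploitation[[id]] <- exploitation_estimate(sp, p_country, e_within, model)
  }
  exploitation_df <- do.call(rbind, lapply(exploitation, function(e) data.frame(
    species_id = e$species_id, persecution = e$persecution,
    p_country = e$p_country, e_within = e$e_within,
    decline_point = e$decline_point, decline_lo = e$decline_lo,
    decline_hi = e$decline_hi, stringsAsFactors = FALSE)))
  rownames(exploitation_df) <- NULL

  # Red List stage
  region <- matrix(TRUE, grid$n_rows, grid$n_cols)  # study region = the grid
  region_fraction <- setNames(
    vapply(species, range_region_fraction, numeric(1),
           region = region, grid = grid), ids)
  # EOO for every species (diagnostic table); criterion B2 is applied only
  # to species routed to the EOO pathway (here: empty t0 habitat, the
  # analog of a no-data void in the forest maps)
  eoo_all <- setNames(vapply(seq_along(ids), function(k) {
    if (sum(esh1[[ids[k]]]$mask) > 0) eoo_convex_hull(esh1[[ids[k]]]$mask, grid)
    else eoo_convex_hull(species[[k]]$range)
  }, numeric(1)), ids)
  routed <- ids[vapply(ids, function(id) isTRUE(changes[[id]]$undefined),
                       logical(1))]
  eoo <- as.list(eoo_all[routed])
  assessment <- assess(species, changes, exploitation, region_fraction,
                       eoo = eoo, eoo_routed = routed,
                       observed_years = landscape$years_between,
                       nt_threshold = th$nt, endemic_threshold = th$endemic)
  summary <- threat_summary(assessment)

  # protection stage (distances always from forest edges here)
  dist_edge <- if (config$source_mode == "forest_edge") dist else
    path_distance(landscape$forest_t1, landscape$elevation,
                  forest_edges(landscape$forest_t1), grid)
  protection <- lapply(esh1, protection_assess, protected = landscape$protected,
                       dist = dist_edge, grid = grid, threshold = th$access_m,
                       vu_km2 = th$pa_vu_km2, cr_km2 = th$pa_cr_km2)
  protection_df <- do.call(rbind, lapply(protection, function(p)
    data.frame(unclass(p), stringsAsFactors = FALSE)))
  rownames(protection_df) <- NULL

  # species-area stage: region-wide forest trajectory
  a0 <- sum(landscape$forest_t0)
  a1 <- sum(landscape$forest_t1)
  annual <- if (a0 > 0) (1 - (a1 / a0)^(1 / landscape$years_between)) else 0
  sar <- sar_table(config$sar$z, species_pool = length(species),
                   area_t0 = a1, annual_rate = annual,
                   years = config$sar$horizon_years)

  results <- list(landscape = landscape, species = species,
                  habitat = habitat_df, access = access_df,
                  exploitation = exploitation_df, assessment = assessment,
                  summary = summary, protection = protection_df, sar = sar,
                  eoo = eoo_all)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_landscape(landscape, file.path(out_dir, "landscape"))
    write_species_set(species, file.path(out_dir, "species"))
    wcsv <- function(df, f) write.csv(df, file.path(out_dir, f), row.names = FALSE)
    wcsv(habitat_df, "habitat_change.csv")
    wcsv(access_df, "access.csv")
    wcsv(exploitation_df, "exploitation.csv")
    wcsv(assessment, "assessment.csv")
    wcsv(protection_df, "protection.csv")
    wcsv(sar, "sar.csv")
    wcsv(data.frame(species_id = names(eoo_all), eoo_km2 = unname(eoo_all),
                    eoo_routed = names(eoo_all) %in% routed,
                    stringsAsFactors = FALSE), "eoo.csv")
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    cfg_path <- file.path(out_dir, "config.yaml")
    yaml::write_yaml(unclass(config), cfg_path)
    prov <- list(seed = config$seed,
                 config_md5 = unname(tools::md5sum(cfg_path)),
                 r_version = paste(R.version$major, R.version$minor, sep = "."),
                 package_version = as.character(utils::packageVersion("forestrisk")))
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(results)
}
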