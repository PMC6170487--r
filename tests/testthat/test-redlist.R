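test_that("assessment window: three generations or ten years", {
  expect_equal(assessment_window(2), 10)
  expect_equal(assessment_window(7), 21)
  expect_warning(w <- assessment_window(NA), "10-year")
  expect_equal(w, 10)
  expect_error(assessment_window(0), "positive")
})

test_that("decline projection follows the proportional decay model", {
  pr <- project_decline(0.15, 15, 10)
  expect_equal(pr$r_annual, 0.01)
  expect_equal(pr$decline_deforestation, 1 - 0.99^10)
  expect_equal(round(pr$decline_deforestation, 4), 0.0956)
  expect_equal(project_decline(0, 15, 30)$decline_deforestation, 0)
  up <- project_decline(-0.1, 15, 10)
  expect_equal(up$decline_deforestation, 0)   # floored rate
  expect_true(up$increase)
  capped <- project_decline(16, 15, 10)       # annual rate >= 1
  expect_equal(capped$decline_deforestation, 1)
  expect_true(capped$rate_capped)
})

test_that("decline classification thresholds (inclusive) and the cap", {
  expect_equal(classify_decline(0.54), "EN")
  expect_equal(classify_decline(1.20), "CR")   # capped at 100%
  expect_equal(classify_decline(0.149999), "LC")
  expect_equal(classify_decline(c(0.15, 0.30, 0.50, 0.80)),
               c("NT", "VU", "EN", "CR"))
  expect_equal(classify_decline(0.17, nt_threshold = 0.2), "LC")
})

test_that("EOO classification uses strict area cutoffs", {
  expect_equal(classify_eoo(499), "EN")
  expect_equal(classify_eoo(1999), "VU")
  expect_true(is.na(classify_eoo(2000)))
  expect_true(is.na(classify_eoo(1e6)))
})

# hand-built cohort shared by the assess() tests
mock_cohort <- function() {
  ids <- sprintf("m%02d", 1:6)
  p_loss <- c(0, 0.15, 0.45, -0.05, 0.30, 0.15)
  pers <- c("none", "none", "none", "low", "high", "medium")
  expl <- c(0, 0, 0, 0.10, 0.85, 0.45)
  species <- Map(function(id, p) make_species(id, rect_ring(0, 0, 1, 1),
                                              generation_length = 10 / 3,
                                              persecution = p), ids, pers)
  changes <- setNames(lapply(seq_along(ids), function(k) list(
    species_id = ids[k], area_t0 = 100, area_t1 = 100 * (1 - p_loss[k]),
    p_loss = p_loss[k], increase = p_loss[k] < 0, undefined = FALSE)), ids)
  exploitation <- setNames(lapply(seq_along(ids), function(k) list(
    species_id = ids[k], persecution = pers[k], p_country = 1, e_within = 1,
    decline_point = expl[k], decline_lo = expl[k] * 0.5,
    decline_hi = min(expl[k] * 1.5, 1))), ids)
  region <- setNames(c(1, 1, 1, 1, 0.5, 0.9), ids)
  list(species = species, changes = changes, exploitation = exploitation,
       region = region, p_loss = p_loss, expl = expl)
}

test_that("cohort assessment matches a hand-computed classification table", {
  co <- mock_cohort()
  # window = max(3 * 10/3, 10) = 10 years; observed 15
  a <- assess(co$species, co$changes, co$exploitation, co$region,
              observed_years = 15)
  # oracle: brute-force per-species expectation
  d_def <- ifelse(co$p_loss < 0, 0, 1 - (1 - co$p_loss / 15)^10)
  total <- pmin(d_def + co$expl, 1)
  want <- ifelse(total >= 0.8, "CR", ifelse(total >= 0.5, "EN",
          ifelse(total >= 0.3, "VU", ifelse(total >= 0.15, "NT", "LC"))))
  expect_equal(a$category_A, want)
  expect_equal(a$final_category, want)   # no B2 inputs here
  expect_equal(a$decline_total_raw, d_def + co$expl)
  # additivity is exact pre-cap
  expect_equal(a$decline_total_raw - a$decline_deforestation,
               a$decline_exploitation)
  # drivers
  expect_equal(a$primary_driver[5], "exploitation")
  expect_equal(a$primary_driver[2], "deforestation")
  # endemism gate: m05 (50% in region) gets no recommendation
  expect_false(a$recommended[5])
  expect_true(a$recommended[1])
  # all-quiet cohort: everyone LC
  quiet <- assess(co$species[1:3], co$changes[c(1, 1, 1)] |>
                    setNames(sprintf("m%02d", 1:3)),
                  setNames(co$exploitation[c(1, 1, 1)], sprintf("m%02d", 1:3)),
                  co$region)
  expect_true(all(quiet$category_A[quiet$decline_total == 0] == "LC"))
})

test_that("category severity is monotone in both decline components", {
  grid_d <- seq(0, 1, by = 0.05)
  sev <- function(cat) match(cat, c("LC", "NT", "VU", "EN", "CR"))
  for (d_ex in c(0, 0.2, 0.6)) {
    cats <- classify_decline(pmin(grid_d + d_ex, 1))
    expect_true(all(diff(sev(cats)) >= 0))
  }
  set.seed(12)
  for (rep in 1:50) {
    d1 <- runif(1); d2 <- runif(1)
    expect_gte(sev(classify_decline(min(d1 + d2, 1))),
               sev(classify_decline(d1)))
  }
})

test_that("uncertainty interval induces ordered categories", {
  co <- mock_cohort()
  a <- assess(co$species, co$changes, co$exploitation, co$region)
  sev <- function(cat) match(cat, c("LC", "NT", "VU", "EN", "CR"))
  lo <- classify_decline(a$decline_lo)
  hi <- classify_decline(a$decline_hi)
  expect_true(all(sev(lo) <= sev(a$category_A)))
  expect_true(all(sev(a$category_A) <= sev(hi)))
})

test_that("EOO-routed species are assessed by criterion B2 alone", {
  sp <- list(make_species("v1", rect_ring(0, 0, 1, 1)))
  a <- assess(sp, changes = list(), exploitation = list(),
              region_fraction = list(v1 = 1), eoo = list(v1 = 450),
              eoo_routed = "v1")
  expect_true(is.na(a$category_A))
  expect_equal(a$category_B2, "EN")
  expect_equal(a$final_category, "EN")
  expect_true(a$eoo_only)
  # missing inputs: species skipped, run continues
  sp2 <- list(make_species("v1", rect_ring(0, 0, 1, 1)),
              make_species("v2", rect_ring(0, 0, 1, 1)))
  a2 <- assess(sp2, changes = list(), exploitation = list(),
               region_fraction = list(v1 = 1, v2 = 1), eoo = list(v1 = 450),
               eoo_routed = "v1")
  expect_equal(nrow(a2), 1)
  expect_equal(attr(a2, "skipped"), "v2")
})

test_that("summary aggregation counts categories and drivers", {
  co <- mock_cohort()
  a <- assess(co$species, co$changes, co$exploitation, co$region)
  s <- threat_summary(a, baseline_threatened = 1)
  expect_equal(s$n_assessed, 6)
  expect_equal(sum(unlist(s$category_counts)), s$n_recommended)
  expect_equal(s$threatened, with(s, category_counts$VU + category_counts$EN +
                                       category_counts$CR))
  expect_equal(s$percent_increase,
               round((s$threatened - 1) / 1 * 100))
  expect_equal(percent_increase(51, 27), 89)
})
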