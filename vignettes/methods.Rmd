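---
title: "Combined deforestation and exploitation threat assessment: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combined deforestation and exploitation threat assessment: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forestrisk)
```

This vignette is the package's own account of its science: the model and
its assumptions, the parameters that matter, what the synthetic-data
generator does and does not emulate, the numerical conventions, and the
design choices that were genuinely open.

## The assessment procedure

Per species, the pipeline computes:

1. **Extent of suitable habitat (ESH)** at two dates: the range polygon
   rasterized by a cell-centre rule, intersected with forest cover and
   (when the species has published elevational limits) an inclusive
   elevation band. The proportional loss between the dates,
   `p = (a0 - a1) / a0`, is the habitat-decline signal.
2. **Accessibility**: a path-distance surface from the forest edge (or a
   road network) across forest cells, and from it `E`, the fraction of
   the species' current ESH within a threshold distance of an access
   point.
3. **Exploitation decline** `R = P * E * H`: the accessible fraction,
   discounted by the fraction of habitat in the country where trapping
   occurs, times a category-specific efficacy with Beta-PERT
   uncertainty.
4. **Red List classification**: the habitat signal is converted to an
   annual rate, projected over max(3 generations, 10 years) with
   proportional decay, added to the exploitation decline, capped at
   100 %, and classified under criterion-A thresholds; species routed to
   the extent-of-occurrence pathway use the criterion-B2 area rules
   instead. Listing recommendations are restricted to regional endemics
   (≥ 80 % of the range inside the study region).
5. **Protection** and **species-area** summaries at landscape level.

## Model assumptions

- **Habitat-population proportionality.** A 1 % yearly habitat loss is
  read as a 1 % yearly population decline. This is linear by
  assumption; threshold or Allee dynamics would make true declines
  steeper near small areas, so the linear reading is conservative in
  that direction.
- **Constant-rate extrapolation.** When three generations exceed the
  observed mapping window, loss is assumed to continue at the observed
  annual rate.
- **Additivity.** Deforestation and exploitation declines add. Totals
  above 100 % are interpreted as complete loss: classification uses the
  capped value, while the raw total is reported alongside
  (`decline_total_raw`) so the cap is auditable.
- **Exploitation geography.** Trapping pressure applies only inside the
  designated country (`P`), only within reach of an access point (`E`),
  and only to species with a non-"none" persecution category; species
  outside all three conditions are conservatively assigned zero
  exploitation impact.

## Parameters, units, defaults

| Parameter | Default | Units | Why |
|---|---|---|---|
| access threshold | 5000 | m | median maximum distance trappers penetrate forest; 7000 is a sensible sensitivity setting (`thresholds$access_m`) |
| observed window | 15 | years | interval between the two forest maps |
| assessment window | max(3G, 10) | years | Red List criterion-A convention; missing generation length G falls back to 10 years with a warning |
| criterion-A thresholds | 0.15 / 0.30 / 0.50 / 0.80 | fraction | NT / VU / EN / CR; inclusive (≥), see below; the NT bar is configurable (`thresholds$nt`, 0.20 being the other published convention) |
| EOO thresholds | 500 / 2000 | km² | criterion-B2 EN / VU bars, strict (<) |
| PA thresholds | 2000 / 10 | km² | VU flag at ≤ 2000 (strict "more than" retained), CR flag at < 10; applied to the hunting-safe core area |
| endemism | 0.8 | fraction | recommendations only when ≥ 80 % of the range is inside the study region |
| PERT shape | 4 | — | standard concentration constant for expert elicitation |
| efficacy low / medium / high | (0, 30, 100) / (30, 50, 100) / (50, 100, 100) | % | modes are the published point efficacies; minima and maxima recovered by inverting the published 95 % intervals; fully overridable via the `efficacy` config section |
| SAR exponent z | 0.18–0.35 | — | spans published species-area slopes for tropical forest biota |

The efficacy recovery can be checked directly:

```{r}
m <- default_efficacy_model()
round(efficacy_quantiles(m$low, c(0.025, 0.975)), 1)     # ~ (6.9, 75.2)
round(efficacy_quantiles(m$medium, c(0.025, 0.975)), 1)  # ~ (34.5, 82)
```

The recovered low and medium intervals match the published bounds to
within 0.5 percentage points. The high category's lower bound computes
to 73.9 against a published 73.7 — consistent with the original bounds
having been estimated by Monte Carlo — and is deliberately not forced to
agree.

## Numerical conventions

- **Rasterization** is by cell centre: a cell belongs to a polygon when
  its centre is inside or on the boundary. Cell centres sit at
  `origin + (j - 0.5, i - 0.5) * cell_size`. One convention, applied to
  ranges and protected areas alike.
- **Elevation clipping** uses inclusive bounds, since published
  elevational limits are inclusive ranges. Forest and elevation clips
  commute, so order is irrelevant.
- **Path distance** uses the 8-connected lattice with surface-length
  weights `sqrt(h^2 + dz^2)` (`h` = cell size axially, `cell_size *
  sqrt(2)` diagonally). This octile metric is the desk-scale analog of a
  GIS path-distance operator; the elevation cost function of such
  operators is tool-specific, and the surface-length weight is this
  package's stated choice. Movement is restricted to forest cells plus
  the source cells themselves: open land is the access medium and
  contributes zero distance.
- **`E` is computed over the current-date ESH**, not the historic range
  polygon: exploitation acts on extant habitat. This is an
  interpretation choice (the alternative denominator is computable from
  the same objects).
- **Uncertainty intervals bracket the point estimate.** With the mode
  elicited at an endpoint (high = (50, 100, 100)), the raw 97.5th
  percentile (99.5) falls below the mode (100); the interval is clamped
  to `[min(q025, mode), max(q975, mode)]`, which also reproduces the
  published upper bound of 100.
- **Classification thresholds are inclusive** (decline ≥ 80 % is CR)
  for consistency with Red List guideline practice, despite the
  strictly-greater wording sometimes used; only exact boundary values
  are affected. The criterion label (A3 vs A4) is a reporting choice
  the package does not resolve.
- **Degenerate inputs** are flagged, not fatal: empty ESH gives an
  `NA` fraction with an `empty` flag; zero time-0 area makes `p`
  undefined and routes the species out of criterion A; a sourceless
  distance computation warns and returns an all-infinite surface.
- Areas are carried at full precision in km²; rounding happens only in
  reports.

## The synthetic world

`generate_landscape()` and `generate_species()` produce the stated test
world: a multi-island equal-area grid (default 200 × 200 cells of 250 m,
matching the resolution of the land-cover products the method consumes),
~70 % initial forest on land, 15 % forest loss over 15 years, elevation
up to 1500 m, a two-country partition with three quarters of the land in
the exploitation country, ~15 % of land under protected areas carrying
IUCN category attributes (I–V rasterized, VI exercised and excluded),
and blob-shaped species ranges whose persecution mix (231 none / 29 low /
24 medium / 24 high per 308) and elevation-limit missingness (88 / 308)
follow the observed composition of the regional avifauna that motivated
the method.

Clearing is sampled without replacement with weight
`exp(-d_edge * edge_bias / cell_size)`. The decay length is
`cell_size / edge_bias`, so larger `edge_bias` concentrates clearing
harder at forest edges and `edge_bias = 0` degenerates to spatially
uniform clearing. (An equivalent parameterization with `edge_bias` in
the denominator would invert the parameter's meaning; the form used here
is the one under which "more bias" means "more edge-concentrated", and
the generator's monotonicity property is stated and tested in those
terms.)

What the generator does **not** emulate: real coastline geometry,
multiple land-cover classes, classification error in the forest maps,
deforestation leakage into protected areas beyond what the forest
rasters encode, riverine or microhabitat structure, and spatial
autocorrelation between species ranges and trapping pressure. A green
test therefore establishes that the pipeline's operations are correct on
landscapes with known ground truth — not that the synthetic world
reproduces any region's empirical decline statistics. One visible
desk-scale artifact: on a 50 km landscape almost all forest lies within
5 km of an edge, so accessible fractions cluster near 1, higher than the
~0.8 means seen on real archipelagos.

Determinism: the landscape consumes `seed`, the species generator
`seed + 1`, so the two streams are independent but jointly reproducible;
a pipeline run is byte-identical given config + seed.

## Design choices where the design was open

- **Criterion B2 routing.** EOO-based classification applies only to
  species routed away from the decline pathway (the analog of no-data
  voids in the forest maps — here, species with empty time-0 habitat);
  computing B2 for every small-range species would swamp a desk-scale
  landscape with area-based listings. The full per-species EOO table is
  still emitted.
- **Protection flags** (`below_vu_threshold`, `below_cr_threshold`) are
  evaluated on the hunting-safe core (protected habitat beyond the
  access threshold), which is the reading under which protected-area
  gaps for persecuted species are reported; plain PA coverage is emitted
  alongside so the other reading costs one comparison.
- **Species-count convention.** Fractions of a species pool are
  truncated toward zero (0.169 × 308 → 52), matching the way published
  percentages pair with published counts; `count_mode = "round"` is
  available.
- **Cap-then-classify.** Declines are capped at 100 % for
  classification; raw totals are reported so either convention can be
  recovered.

## Known limitations

- The octile lattice metric overestimates true Euclidean shortest paths
  by up to ~8 % on flat terrain; distances are comparable across
  species but are not geodesic.
- Persecution is categorical; within-category heterogeneity in trapping
  pressure is not modelled.
- No population-viability or criterion-E model; the species-area
  projection is reported for context, not used for listing.
- Protected areas affect only the coverage statistics; they do not slow
  simulated forest loss.
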