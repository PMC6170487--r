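#' Beta-PERT parameters for an expert-elicited efficacy
#'
#' A PERT distribution expresses an expert's minimum / most-likely /
#' maximum estimate as a Beta distribution rescaled to
#' `[minimum, maximum]`, with concentration controlled by `shape`
#' (conventionally 4). Values are percentages of population suppressed
#' within the accessible zone.
#'
#' @param minimum,mode,maximum percentages in `[0, 100]` with
#'   `minimum <= mode <= maximum`.
#' @param shape concentration constant, default 4.
#' @return object of class `pert_params`.
#' @export
pert_params <- function(minimum, mode, maximum, shape = 4) {
  stopifnot(0 <= minimum, minimum <= mode, mode <= maximum, maximum <= 100,
            shape > 0)
  structure(list(minimum = minimum, mode = mode, maximum = maximum,
                 shape = shape), class = "pert_params")
}

#' Beta shape parameters of a PERT distribution
#'
#' `alpha = 1 + shape * (mode - min) / (max - min)`,
#' `beta  = 1 + shape * (max - mode) / (max - min)`; the distribution is
#' `Beta(alpha, beta)` rescaled to `[min, max]`.
#'
#' @param params a [pert_params()].
#' @return named numeric `c(alpha, beta)`; errors when `max == min`
#'   (degenerate point mass — handled by [efficacy_quantiles()]).
#' @export
pert_to_beta <- function(params) {
  stopifnot(inherits(params, "pert_params"))
  rng <- params$maximum - params$minimum
  if (rng <= 0) stop("degenerate PERT (maximum = minimum) has no Beta form",
                     call. = FALSE)
  c(alpha = 1 + params$shape * (params$mode - params$minimum) / rng,
    beta  = 1 + params$shape * (params$maximum - params$mode) / rng)
}

#' Quantiles of a PERT efficacy distribution
#'
#' Closed-form quantiles via the inverse regularized incomplete beta
#' function (`qbeta`), rescaled to the elicited range. A degenerate
#' distribution (max = min) returns the mode at every probability.
#'
#' @param params a [pert_params()].
#' @param probs probabilities in (0, 1).
#' @return efficacies in percent, same length as `probs`.
#' @export
efficacy_quantiles <- function(params, probs) {
  stopifnot(all(probs > 0 & probs < 1))
  if (params$maximum == params$minimum) return(rep(params$mode, length(probs)))
  ab <- pert_to_beta(params)
  params$minimum + (params$maximum - params$minimum) *
    qbeta(probs, ab["alpha"], ab["beta"])
}

#' Monte Carlo draws from a PERT efficacy distribution
#'
#' Cross-check estimator for [efficacy_quantiles()].
#'
#' @param n number of draws.
#' @param params a [pert_params()].
#' @return numeric vector of efficacies in percent.
#' @export
rpert <- function(n, params) {
  if (params$maximum == params$minimum) return(rep(params$mode, n))
  ab <- pert_to_beta(params)
  params$minimum + (params$maximum - params$minimum) *
    rbeta(n, ab["alpha"], ab["beta"])
}

#' Default persecution-category efficacy model
#'
#' Modes 30 / 50 / 100 percent for low / medium / high persecution; the
#' elicited minima and maxima are recovered by inverting the published 95%
#' intervals (low 6.9-75.2, medium 34.5-82, high 73.7-100). Species with
#' persecution "none" have efficacy 0 by assumption. Fully overridable.
#'
#' @return named list of [pert_params()] for `low`, `medium`, `high`.
#' @export
default_efficacy_model <- function() {
  list(low    = pert_params(0, 30, 100),
       medium = pert_params(30, 50, 100),
       high   = pert_params(50, 100, 100))
}

#' Population decline from exploitation
#'
#' The product `P * E * H`: the fraction of the range in the exploitation
#' country, the fraction of habitat within trapper reach, and the efficacy
#' (as a fraction) of exploitation in the reached zone.
#'
#' @param p_country,e_within,efficacy fractions in `[0, 1]`.
#' @return decline as a fraction in `[0, 1]`.
#' @export
exploitation_decline <- function(p_country, e_within, efficacy) {
  stopifnot(all(p_country >= 0 & p_country <= 1),
            all(e_within >= 0 & e_within <= 1),
            all(efficacy >= 0 & efficacy <= 1))
  p_country * e_within * efficacy
}

#' Exploitation decline estimate with 95% uncertainty interval
#'
#' Applies the decline product at the efficacy mode and at the 2.5th /
#' 97.5th efficacy percentiles of the species' persecution category.
#' Persecution "none" gives zero decline with a degenerate interval.
#'
#' @param species a species record with `species_id` and `persecution`.
#' @param p_country fraction of the species' habitat in the exploitation
#'   country.
#' @param e_within fraction of habitat within trapper reach (see
#'   [fraction_within()]).
#' @param model efficacy model as from [default_efficacy_model()].
#' @return list: `species_id`, `persecution`, `p_country`, `e_within`,
#'   `decline_point`, `decline_lo`, `decline_hi`.
#' @export
exploitation_estimate <- function(species, p_country, e_within,
                                  model = default_efficacy_model()) {
  cat_ <- species$persecution
  if (cat_ == "none") {
    eff <- c(0, 0, 0)
  } else {
    pp <- model[[cat_]]
    if (is.null(pp)) stop(sprintf("no efficacy parameters for category '%s'", cat_),
                          call. = FALSE)
    q <- efficacy_quantiles(pp, c(0.025, 0.975))
    # the 95% interval must bracket the point estimate: with the mode at
    # an elicitation endpoint (e.g. high = (50, 100, 100)) the raw 97.5th
    # percentile can fall below the mode
    eff <- c(pp$mode, min(q[1], pp$mode), max(q[2], pp$mode)) / 100
  }
  d <- exploitation_decline(p_country, e_within, eff)
  list(species_id = species$species_id, persecution = cat_,
       p_country = p_country, e_within = e_within,
       decline_point = d[1], decline_lo = d[2], decline_hi = d[3])
}

#' Cumulative exploitation suppression by distance from access points
#'
#' Decline as a function of the access threshold: for each distance bin
#' `d` in `(0, max_distance]`, the decline product with
#' `fraction_within(d)` in place of the fixed-threshold exposure. The
#' curve is non-decreasing in distance and reaches the species' point
#' estimate at `max_distance`.
#'
#' @param species species record (for id and persecution category).
#' @param esh [compute_esh()] result for the current date.
#' @param dist [path_distance()] result.
#' @param p_country fraction of habitat in the exploitation country.
#' @param model efficacy model.
#' @param max_distance metres, default 5000.
#' @param n_bins number of distance bins, default 50.
#' @return data.frame with `distance_m` and `decline` (starting at the
#'   0-distance row with decline 0); `NULL` with a warning when the ESH is
#'   empty.
#' @export
cumulative_suppression_profile <- function(species, esh, dist, p_country,
                                           model = default_efficacy_model(),
                                           max_distance = 5000, n_bins = 50) {
  if (sum(esh$mask) == 0) {
    warning(sprintf("species %s: empty habitat, no suppression profile",
                    esh$species_id))
    return(NULL)
  }
  eff <- if (species$persecution == "none") 0 else
    model[[species$persecution]]$mode / 100
  d_vals <- dist$distance[esh$mask]
  n <- length(d_vals)
  ds <- seq(0, max_distance, length.out = n_bins + 1)
  frac <- vapply(ds, function(th) sum(d_vals <= th) / n, numeric(1))
  frac[1] <- 0  # distance 0: no penetration yet
  data.frame(species_id = esh$species_id, distance_m = ds,
             decline = exploitation_decline(p_country, frac, eff))
}
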