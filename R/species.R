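#' Life-history and observation parameters for the surrogate stock
#'
#' Bundles the parameters of the single-species stochastic size-spectrum
#' model: allometric somatic growth tapered at the asymptotic mass,
#' `g(w) = growth_coefficient * w^growth_exponent * (1 - w/asymptotic_mass)`;
#' allometric background mortality
#' `mu(w) = background_mortality_coefficient * w^mortality_exponent`;
#' Beverton-Holt recruitment driven by spawner biomass (the biomass above
#' `fishing_selectivity_threshold`) with a mean-one lognormal multiplier
#' drawn once per calendar year; and the observation cutoff below which
#' individuals are invisible to the survey-style annual summaries.
#'
#' The defaults describe a cod-like demersal stock on the default
#' `build_size_grid()`. Recruits enter at the smallest grid mass (5 g,
#' roughly an age-1 survey recruit rather than an egg), reach the 10 g
#' observation cutoff within about a year, and mature into the fished
#' size range after roughly a decade, so that fishing depresses the
#' observable stock below 30% of its unfished level while the stock
#' persists, and release of fishing produces a lagged recovery over one
#' to several decades. The half-saturation default equals one tenth of
#' `recruitment_capacity` times the unfished spawner biomass per recruit
#' on the default grid, giving strong but finite compensation.
#'
#' @param growth_coefficient Growth scale `g0` in grams per gram^`b` per
#'   year; with `growth_exponent = 1` this is the mass-specific growth rate
#'   of small fish per year.
#' @param growth_exponent Allometric growth exponent `b` (dimensionless).
#' @param asymptotic_mass Mass in grams at which somatic growth falls to
#'   zero.
#' @param background_mortality_coefficient Mortality scale `mu0` per year at
#'   1 g.
#' @param mortality_exponent Allometric mortality exponent (dimensionless,
#'   typically negative: small fish die faster).
#' @param recruitment_capacity Maximum recruitment rate in individuals per
#'   year (the Beverton-Holt asymptote). Zero switches recruitment off.
#' @param recruitment_half_saturation Spawner biomass in grams at which
#'   recruitment reaches half of `recruitment_capacity`.
#' @param recruitment_noise_sigma Standard deviation (log scale,
#'   dimensionless) of the annual lognormal recruitment multiplier. The
#'   multiplier is mean-one corrected: `exp(sigma * z - sigma^2/2)`.
#' @param egg_mass Mass in grams at which recruits enter the spectrum; must
#'   not exceed the smallest grid center.
#' @param fishing_selectivity_threshold Mass in grams above which fishing
#'   mortality applies (knife-edge selectivity); also used as the maturity
#'   threshold defining spawner biomass.
#' @param observation_cutoff Mass in grams above which individuals count
#'   towards the annual biomass / body-size summaries (default 10 g, the
#'   typical minimum size retained by trawl surveys).
#'
#' @return An object of class `species_params` (a named list).
#' @export
species_params <- function(growth_coefficient = 1.2,
                           growth_exponent = 0.75,
                           asymptotic_mass = 8000,
                           background_mortality_coefficient = 0.35,
                           mortality_exponent = 0,
                           recruitment_capacity = 1e6,
                           recruitment_half_saturation = 6.82e6,
                           recruitment_noise_sigma = 0.05,
                           egg_mass = 5,
                           fishing_selectivity_threshold = 500,
                           observation_cutoff = 10) {
  p <- list(
    growth_coefficient = growth_coefficient,
    growth_exponent = growth_exponent,
    asymptotic_mass = asymptotic_mass,
    background_mortality_coefficient = background_mortality_coefficient,
    mortality_exponent = mortality_exponent,
    recruitment_capacity = recruitment_capacity,
    recruitment_half_saturation = recruitment_half_saturation,
    recruitment_noise_sigma = recruitment_noise_sigma,
    egg_mass = egg_mass,
    fishing_selectivity_threshold = fishing_selectivity_threshold,
    observation_cutoff = observation_cutoff
  )
  for (nm in names(p)) {
    if (!is_scalar_number(p[[nm]])) {
      stop_invalid("species parameter `%s` must be a single finite number", nm)
    }
  }
  masses <- c("asymptotic_mass", "egg_mass", "fishing_selectivity_threshold",
              "observation_cutoff")
  for (nm in masses) {
    if (p[[nm]] <= 0) stop_invalid("species parameter `%s` must be positive", nm)
  }
  if (p$recruitment_noise_sigma < 0) {
    stop_invalid("`recruitment_noise_sigma` must be >= 0")
  }
  if (p$growth_coefficient < 0 || p$background_mortality_coefficient < 0 ||
      p$recruitment_capacity < 0 || p$recruitment_half_saturation < 0) {
    stop_invalid("rate and capacity parameters must be non-negative")
  }
  structure(p, class = "species_params")
}

#' @export
print.species_params <- function(x, ...) {
  cat("<species_params>\n")
  cat(sprintf("  growth: g(w) = %g * w^%g * (1 - w/%g) g/yr\n",
              x$growth_coefficient, x$growth_exponent, x$asymptotic_mass))
  cat(sprintf("  mortality: mu(w) = %g * w^%g per yr\n",
              x$background_mortality_coefficient, x$mortality_exponent))
  cat(sprintf("  recruitment: BH(Rmax = %g /yr, B50 = %g g), lognormal sigma = %g\n",
              x$recruitment_capacity, x$recruitment_half_saturation,
              x$recruitment_noise_sigma))
  cat(sprintf("  egg %g g | fished above %g g | observed above %g g\n",
              x$egg_mass, x$fishing_selectivity_threshold, x$observation_cutoff))
  invisible(x)
}

# somatic growth rate g(w), grams per year
growth_rate <- function(params, w) {
  params$growth_coefficient * w^params$growth_exponent *
    pmax(0, 1 - w / params$asymptotic_mass)
}

# background (natural) mortality mu(w), per year
mortality_rate <- function(params, w) {
  params$background_mortality_coefficient * w^params$mortality_exponent
}
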