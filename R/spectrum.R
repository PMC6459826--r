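#' Create a simulation state
#'
#' A state holds the abundance density `n` (individuals per gram) in each
#' size class, plus the calendar year it describes. The default abundance
#' is a steep power-law guess, `n(w) ~ w^-2`; burn-in iteration forgets the
#' starting point.
#'
#' @param grid A [build_size_grid()] object.
#' @param abundance Optional numeric vector of abundance densities
#'   (individuals per gram), one per size class.
#' @param year Calendar year the state refers to.
#' @return A list with elements `n` (numeric) and `year`.
#' @export
new_sim_state <- function(grid, abundance = NULL, year = NA_integer_) {
  stopifnot(inherits(grid, "size_grid"))
  if (is.null(abundance)) abundance <- 1e3 * grid$centers^-2
  if (length(abundance) != grid$n_classes) {
    stop_invalid("`abundance` must have one entry per size class (%d)",
                 grid$n_classes)
  }
  if (any(!is.finite(abundance)) || any(abundance < 0)) {
    stop_invalid("abundances must be finite and non-negative")
  }
  list(n = as.numeric(abundance), year = year)
}

# spawner biomass in grams: mass above the selectivity/maturity threshold
spawner_biomass <- function(n, grid, params) {
  mature <- grid$centers > params$fishing_selectivity_threshold
  sum(n[mature] * grid$centers[mature] * grid$widths[mature])
}

# one explicit upwind sub-step given precomputed growth and decay factors;
# `decay` is exp(-(mu + F * selected) * dt)
step_spectrum_impl <- function(n, params, grid, g, decay, dt,
                               recruit_multiplier) {
  rec <- 0
  if (params$recruitment_capacity > 0) {
    ssb <- spawner_biomass(n, grid, params)
    if (ssb > 0) {
      rec <- params$recruitment_capacity * ssb /
        (ssb + params$recruitment_half_saturation) * recruit_multiplier
    }
  }
  flux <- g * n
  nk <- grid$n_classes
  n <- n + dt * (c(rec, flux[-nk]) - flux) / grid$widths
  pmax(n * decay, 0)
}

# CFL safety of the explicit upwind growth step; errors naming the worst class
check_cfl <- function(g, grid, dt) {
  cfl <- g * dt / grid$widths
  if (any(cfl > 1 + 1e-12)) {
    i <- which.max(cfl)
    stop_invalid(paste0(
      "CFL condition violated in size class %d (center %.4g g): ",
      "g*dt/dw = %.3f exceeds 1; reduce `dt` or the growth rate"),
      i, grid$centers[i], cfl[i])
  }
  invisible(cfl)
}

#' Advance the size spectrum by one sub-step
#'
#' First-order explicit upwind differencing of the growth transport term
#' d(gN)/dw of the McKendrick-von Foerster equation, followed by exact
#' exponential decay under background plus fishing mortality. Recruitment
#' enters the smallest size class as a boundary flux: Beverton-Holt in the
#' current spawner biomass, multiplied by `recruit_multiplier` (the annual
#' lognormal deviate, drawn once per calendar year by [run_simulation()]).
#'
#' @param state A state from [new_sim_state()].
#' @param params A [species_params()] object.
#' @param grid A [build_size_grid()] object.
#' @param F Fishing mortality per year applied above the selectivity
#'   threshold.
#' @param dt Sub-step length in years.
#' @param recruit_multiplier Multiplier on the Beverton-Holt recruitment
#'   rate for this step (default 1).
#' @return The advanced state.
#' @export
step_spectrum <- function(state, params, grid, F = 0, dt = 0.1,
                          recruit_multiplier = 1) {
  stopifnot(inherits(params, "species_params"), inherits(grid, "size_grid"))
  if (!is_scalar_number(dt) || dt <= 0) stop_invalid("`dt` must be > 0")
  if (!is_scalar_number(F) || F < 0) stop_invalid("`F` must be >= 0")
  w <- grid$centers
  g <- growth_rate(params, w)
  check_cfl(g, grid, dt)
  sel <- w > params$fishing_selectivity_threshold
  decay <- exp(-(mortality_rate(params, w) + F * sel) * dt)
  state$n <- step_spectrum_impl(state$n, params, grid, g, decay, dt,
                                recruit_multiplier)
  state
}

#' Deterministic quasi-steady state under constant fishing
#'
#' Iterates the deterministic model (recruitment noise off) year by year
#' until the relative change in total biomass between successive years
#' drops below `tol`. Used as the fast burn-in: the equilibrium can be
#' computed once and shared across replicates.
#'
#' @inheritParams step_spectrum
#' @param tol Relative annual biomass change below which the state is
#'   declared converged.
#' @param max_years Iteration cap; a warning is issued if reached.
#' @return A converged simulation state.
#' @export
equilibrium_state <- function(params, grid = build_size_grid(), F = 0,
                              dt = 0.1, tol = 1e-6, max_years = 3000) {
  state <- new_sim_state(grid)
  w <- grid$centers
  g <- growth_rate(params, w)
  check_cfl(g, grid, dt)
  sel <- w > params$fishing_selectivity_threshold
  decay <- exp(-(mortality_rate(params, w) + F * sel) * dt)
  steps <- steps_per_year(dt)
  b_prev <- sum(state$n * w * grid$widths)
  for (y in seq_len(max_years)) {
    for (s in seq_len(steps)) {
      state$n <- step_spectrum_impl(state$n, params, grid, g, decay, dt, 1)
    }
    b <- sum(state$n * w * grid$widths)
    if (b_prev > 0 && abs(b - b_prev) / b_prev < tol && y > 5) {
      return(state)
    }
    b_prev <- b
  }
  warning("equilibrium_state: biomass had not converged after ",
          max_years, " years")
  state
}

steps_per_year <- function(dt) {
  steps <- round(1 / dt)
  if (abs(steps * dt - 1) > 1e-9) {
    stop_invalid("`dt` must divide one year evenly (got %g)", dt)
  }
  steps
}

#' Annual survey-style summary of one state
#'
#' Restricts to the observable size classes (centers strictly above the
#' observation cutoff) and returns the biomass together with the
#' number-weighted mean and standard deviation of body mass. Counts per
#' class are `n * width`; the SD uses the sample (`n - 1`) analogue on
#' those counts. Years with no observable individuals report zero biomass
#' and missing sizes.
#'
#' @inheritParams step_spectrum
#' @return A list with `biomass` (g), `mean_size` (g), `sd_size` (g) and
#'   `observable` (logical).
#' @export
observable_summary <- function(state, grid, params) {
  obs <- grid$centers > params$observation_cutoff
  w <- grid$centers[obs]
  counts <- state$n[obs] * grid$widths[obs]
  total <- sum(counts)
  if (total <= 0) {
    return(list(biomass = 0, mean_size = NA_real_, sd_size = NA_real_,
                observable = FALSE))
  }
  biomass <- sum(counts * w)
  mean_size <- biomass / total
  sd_size <- if (total > 1) {
    sqrt(sum(counts * (w - mean_size)^2) / (total - 1))
  } else {
    NA_real_
  }
  list(biomass = biomass, mean_size = mean_size, sd_size = sd_size,
       observable = TRUE)
}

#' Run one replicate of the collapse-and-release simulation
#'
#' Advances the stochastic size spectrum through the fishing schedule and
#' records one survey-style summary per calendar year ([observable_summary()]
#' taken after the year's sub-steps). The lognormal recruitment deviate is
#' drawn once per calendar year; runs with the same seed are bit-identical.
#'
#' With `burn_in = "fast"` (the default) the pre-1967 burn-in is replaced
#' by the deterministic unfished equilibrium ([equilibrium_state()]), which
#' may be precomputed and passed as `init_state`; with `burn_in = "full"`
#' the model is integrated, with recruitment noise, from the burn-in start
#' year.
#'
#' @inheritParams step_spectrum
#' @param schedule A [make_fishing_schedule()] object.
#' @param seed Integer seed for the recruitment-noise stream.
#' @param burn_in `"fast"` or `"full"`.
#' @param init_state Optional starting state for `burn_in = "fast"`.
#' @param record_from First calendar year to record (defaults to the first
#'   simulated year).
#' @return An `annual_series` tibble with columns `year`, `biomass` (g),
#'   `mean_size` (g), `sd_size` (g), `observable`.
#' @export
run_simulation <- function(params, schedule, grid = build_size_grid(),
                           seed = 1, burn_in = c("fast", "full"),
                           init_state = NULL, dt = 0.1, record_from = NULL) {
  stopifnot(inherits(params, "species_params"),
            inherits(schedule, "fishing_schedule"),
            inherits(grid, "size_grid"))
  burn_in <- match.arg(burn_in)
  steps <- steps_per_year(dt)
  if (!is_scalar_number(seed) || abs(seed) >= 2^31) {
    stop_invalid("`seed` must be a single integer below 2^31")
  }
  set.seed(as.integer(seed))

  yr <- schedule$years
  if (burn_in == "fast") {
    state <- init_state %||% equilibrium_state(params, grid, F = 0, dt = dt)
    start_year <- yr$historic_start
  } else {
    state <- new_sim_state(grid)
    start_year <- yr$burn_in_start
  }
  record_from <- record_from %||% start_year
  years <- seq.int(start_year, yr$end_year)

  w <- grid$centers
  g <- growth_rate(params, w)
  check_cfl(g, grid, dt)
  sel <- w > params$fishing_selectivity_threshold
  mu <- mortality_rate(params, w)
  sigma <- params$recruitment_noise_sigma

  keep <- years >= record_from
  out_year <- years[keep]
  nb <- length(out_year)
  biomass <- mean_size <- sd_size <- numeric(nb)
  observable <- logical(nb)
  j <- 0L

  for (y in years) {
    z <- rnorm(1)
    xi <- exp(sigma * z - sigma^2 / 2)
    Fy <- schedule_F(schedule, y)
    decay <- exp(-(mu + Fy * sel) * dt)
    for (s in seq_len(steps)) {
      state$n <- step_spectrum_impl(state$n, params, grid, g, decay, dt, xi)
    }
    if (y >= record_from) {
      j <- j + 1L
      smry <- observable_summary(state, grid, params)
      biomass[j] <- smry$biomass
      mean_size[j] <- smry$mean_size
      sd_size[j] <- smry$sd_size
      observable[j] <- smry$observable
    }
  }
  state$year <- yr$end_year

  out <- tibble(year = out_year, biomass = biomass, mean_size = mean_size,
                sd_size = sd_size, observable = observable)
  attr(out, "observation_cutoff") <- params$observation_cutoff
  attr(out, "final_state") <- state
  class(out) <- c("annual_series", class(out))
  out
}
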