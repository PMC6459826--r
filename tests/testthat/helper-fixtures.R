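# Shared fixtures, built once per test run. Short schedules keep the
# simulator tests fast; the full-horizon ensemble lives only in the
# acceptance tests.

short_years <- function(end_year = 2000) {
  list(burn_in_start = 1667L, historic_start = 1967L, plateau_start = 1990L,
       release_start = 1995L, end_year = as.integer(end_year))
}

# parameters with every process switched off except what a test enables
inert_params <- function(...) {
  args <- list(...)
  defaults <- list(growth_coefficient = 0, growth_exponent = 1,
                   asymptotic_mass = 40000,
                   background_mortality_coefficient = 0,
                   mortality_exponent = 0, recruitment_capacity = 0,
                   recruitment_half_saturation = 1, recruitment_noise_sigma = 0,
                   egg_mass = 5, fishing_selectivity_threshold = 500,
                   observation_cutoff = 10)
  do.call(species_params, utils::modifyList(defaults, args))
}

small_grid <- function() build_size_grid(20, 5, 4000)

cached <- local({
  env <- new.env()
  function(key, expr) {
    if (is.null(env[[key]])) env[[key]] <- force(expr)
    env[[key]]
  }
})

default_equilibrium <- function() {
  cached("eq_default", equilibrium_state(species_params(), build_size_grid()))
}

# a small but full-horizon ensemble shared by the evaluation tests
eval_ensemble <- function() {
  cached("eval_ens", generate_ensemble(n_reps = 3, treatments = c(0, 0.1),
                                       base_seed = 7))
}
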