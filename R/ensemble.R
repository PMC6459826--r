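#' Default release-rate treatments
#'
#' Fractions of the plateau fishing mortality removed per year after the
#' release year: the control (0) plus linear declines reaching zero fishing
#' over 50, 40, 30, 20 and 10 years.
#'
#' @return Numeric vector of decline rates (fraction per year).
#' @export
default_treatments <- function() c(0, 0.02, 0.025, 0.033, 0.05, 0.10)

treatment_label <- function(rate) {
  ifelse(rate == 0, "control", sprintf("decline_%g", rate))
}

#' Replicate/seed plan for an ensemble
#'
#' Enumerates the (treatment, replicate) grid and the derived seeds.
#' Seeds depend only on the replicate index (`base_seed + replicate`), so
#' treatments share recruitment-noise streams within a replicate index,
#' pairing the noise across treatments.
#'
#' @param treatments Numeric vector of decline rates (0 = control).
#' @param n_reps Replicates per treatment.
#' @param base_seed Integer base seed.
#' @return A tibble with columns `treatment`, `decline_rate`, `replicate`,
#'   `seed`.
#' @export
ensemble_plan <- function(treatments = default_treatments(), n_reps = 300,
                          base_seed = 1) {
  if (!is_scalar_number(n_reps) || n_reps < 1 || n_reps != round(n_reps)) {
    stop_invalid("`n_reps` must be a single integer >= 1")
  }
  if (!is.numeric(treatments) || length(treatments) < 1 ||
      anyDuplicated(treatments)) {
    stop_invalid("`treatments` must be a non-empty set of distinct decline rates")
  }
  if (base_seed + n_reps >= 2^31) {
    stop_invalid("`base_seed` + `n_reps` must stay below 2^31")
  }
  plan <- tidyr::expand_grid(decline_rate = as.numeric(treatments),
                             replicate = seq_len(n_reps))
  plan$treatment <- treatment_label(plan$decline_rate)
  plan$seed <- base_seed + plan$replicate
  plan[, c("treatment", "decline_rate", "replicate", "seed")]
}

#' Simulate an ensemble of collapse-and-release replicates
#'
#' Runs [run_simulation()] for every (treatment, replicate) pair of
#' [ensemble_plan()]. With `burn_in = "fast"` the deterministic unfished
#' equilibrium is computed once and shared by all replicates.
#'
#' @inheritParams ensemble_plan
#' @inheritParams run_simulation
#' @param plateau_F Plateau fishing mortality shared by all treatments.
#' @param years Phase boundary years, as [default_phase_years()].
#' @return A tidy tibble with columns `treatment`, `decline_rate`,
#'   `replicate`, `year`, `biomass`, `mean_size`, `sd_size`, `observable`.
#' @export
generate_ensemble <- function(params = species_params(),
                              treatments = default_treatments(),
                              n_reps = 50, base_seed = 1, plateau_F = 1.0,
                              years = default_phase_years(),
                              grid = build_size_grid(),
                              burn_in = c("fast", "full"), dt = 0.1,
                              record_from = NULL,
                              historic_peak_fraction = 1,
                              historic_peak_year = 2000) {
  burn_in <- match.arg(burn_in)
  plan <- ensemble_plan(treatments, n_reps, base_seed)
  init <- if (burn_in == "fast") {
    equilibrium_state(params, grid, F = 0, dt = dt)
  } else {
    NULL
  }
  schedules <- lapply(as.numeric(treatments), function(r) {
    make_fishing_schedule(plateau_F = plateau_F, decline_rate = r,
                          years = years,
                          historic_peak_fraction = historic_peak_fraction,
                          historic_peak_year = historic_peak_year)
  })
  names(schedules) <- treatment_label(as.numeric(treatments))

  pieces <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    series <- run_simulation(params, schedules[[plan$treatment[i]]],
                             grid = grid, seed = plan$seed[i],
                             burn_in = burn_in, init_state = init, dt = dt,
                             record_from = record_from)
    pieces[[i]] <- tibble(treatment = plan$treatment[i],
                          decline_rate = plan$decline_rate[i],
                          replicate = plan$replicate[i],
                          as_tibble(series))
  }
  dplyr::bind_rows(pieces)
}

#' Write / read a tidy ensemble CSV
#'
#' @param ensemble A tibble from [generate_ensemble()].
#' @param path File path.
#' @return `read_ensemble()` returns the ensemble tibble; `write_ensemble()`
#'   returns `path` invisibly.
#' @export
write_ensemble <- function(ensemble, path) {
  utils::write.csv(as.data.frame(ensemble), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(path) {
  df <- utils::read.csv(path)
  required <- c("treatment", "decline_rate", "replicate", "year", "biomass",
                "mean_size", "sd_size")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop_invalid("ensemble file lacks required column(s): %s",
                 paste(missing, collapse = ", "))
  }
  as_tibble(df)
}
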