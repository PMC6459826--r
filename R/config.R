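#' Default scenario configuration
#'
#' The scaled-down profile used for interactive work: 50 replicates per
#' treatment with the fast (run-to-convergence) burn-in. The paper-scale
#' profile (300 replicates, full 300-year stochastic burn-in) ships as
#' `paper_config.yaml` in the package's `extdata`.
#'
#' @return A nested list mirroring the YAML scenario schema: `grid`,
#'   `species`, `years`, `plateau_F`, `treatments`, `n_reps`, `base_seed`,
#'   `burn_in`.
#' @export
scenario_defaults <- function() {
  list(
    grid = list(n_classes = 100, w_min = 5, w_max = 40000),
    species = unclass(species_params()),
    years = default_phase_years(),
    plateau_F = 1.0,
    treatments = default_treatments(),
    n_reps = 50,
    base_seed = 1,
    burn_in = "fast"
  )
}

#' Read a YAML scenario configuration
#'
#' Unspecified fields fall back to [scenario_defaults()]; nested fields
#' (grid, species, years) are merged per key.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return A validated configuration list of class `scenario_config`.
#' @export
read_scenario_config <- function(path = NULL) {
  cfg <- scenario_defaults()
  if (!is.null(path)) {
    if (!file.exists(path)) stop_invalid("config file not found: %s", path)
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown)) {
      stop_invalid("unknown config field(s): %s", paste(unknown, collapse = ", "))
    }
    for (nm in names(user)) {
      cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(user[[nm]])) {
        utils::modifyList(cfg[[nm]], user[[nm]])
      } else {
        user[[nm]]
      }
    }
  }
  # YAML flow sequences of mixed int/real arrive as lists
  cfg$treatments <- as.numeric(unlist(cfg$treatments))
  # constructors validate their own slices
  cfg$species <- do.call(species_params, cfg$species)
  cfg$grid <- do.call(build_size_grid, cfg$grid)
  if (!cfg$burn_in %in% c("fast", "full")) {
    stop_invalid("`burn_in` must be \"fast\" or \"full\"")
  }
  invisible(make_fishing_schedule(cfg$plateau_F, 0, cfg$years))
  structure(cfg, class = "scenario_config")
}

manifest_write <- function(out_dir, stage, outputs, seed, config_path = NULL,
                           extra = list(), elapsed = NA_real_) {
  manifest <- c(list(
    stage = stage,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("recoverews")),
    base_seed = seed,
    config_md5 = if (!is.null(config_path)) {
      unname(tools::md5sum(config_path))
    } else {
      NA_character_
    },
    outputs = outputs,
    elapsed_seconds = round(elapsed, 2)
  ), extra)
  path <- file.path(out_dir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Simulate an ensemble from a scenario configuration
#'
#' Writes `ensemble.csv` (tidy per-year records) and a JSON run manifest
#' to `out_dir`. Rerunning with the same configuration and seed produces a
#' byte-identical ensemble file.
#'
#' @param config_path YAML scenario file, or `NULL` for defaults.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional override of the configured base seed.
#' @param reps Optional override of the configured replicate count.
#' @return The ensemble tibble, invisibly.
#' @export
cli_simulate <- function(config_path = NULL, out_dir = ".", seed = NULL,
                         reps = NULL) {
  t0 <- Sys.time()
  cfg <- read_scenario_config(config_path)
  if (!is.null(seed)) cfg$base_seed <- seed
  if (!is.null(reps)) cfg$n_reps <- reps
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ens <- generate_ensemble(params = cfg$species, treatments = cfg$treatments,
                           n_reps = cfg$n_reps, base_seed = cfg$base_seed,
                           plateau_F = cfg$plateau_F, years = cfg$years,
                           grid = cfg$grid, burn_in = cfg$burn_in)
  out_csv <- file.path(out_dir, "ensemble.csv")
  write_ensemble(ens, out_csv)
  counts <- table(ens$treatment[!duplicated(paste(ens$treatment, ens$replicate))])
  message("simulated replicates per treatment: ",
          paste(names(counts), counts, sep = "=", collapse = ", "))
  manifest_write(out_dir, "simulate", outputs = "ensemble.csv",
                 seed = cfg$base_seed, config_path = config_path,
                 extra = list(n_reps = cfg$n_reps,
                              treatments = cfg$treatments,
                              plateau_F = cfg$plateau_F),
                 elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(ens)
}

#' Analyze an ensemble CSV: indicators, composites, detections
#'
#' Writes `composites.csv`, `results.csv`, `replicates.csv` and a manifest
#' to `out_dir`.
#'
#' @param ensemble_csv Path to a tidy ensemble CSV.
#' @param out_dir Output directory.
#' @param threshold_sigma,consecutive_k Detection settings.
#' @param analysis_start_year,release_start Analysis windows.
#' @return The [ews_analysis()] object, invisibly.
#' @export
cli_analyze <- function(ensemble_csv, out_dir = ".", threshold_sigma = 2,
                        consecutive_k = 2, analysis_start_year = 2010,
                        release_start = 2040) {
  t0 <- Sys.time()
  ens <- read_ensemble(ensemble_csv)
  cfg <- detection_config(threshold_sigma = threshold_sigma,
                          consecutive_k = consecutive_k,
                          training = c(analysis_start_year, release_start - 1),
                          assessment = c(release_start, release_start + 50))
  analysis <- ews_analysis(ens, cfg = cfg,
                           analysis_start_year = analysis_start_year,
                           release_start = release_start)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(analysis$composites),
                   file.path(out_dir, "composites.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(analysis$results),
                   file.path(out_dir, "results.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(analysis$replicates),
                   file.path(out_dir, "replicates.csv"), row.names = FALSE)
  manifest_write(out_dir, "analyze",
                 outputs = c("composites.csv", "results.csv",
                             "replicates.csv"),
                 seed = NA,
                 extra = list(threshold_sigma = threshold_sigma,
                              consecutive_k = consecutive_k,
                              analysis_start_year = analysis_start_year,
                              release_start = release_start),
                 elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(analysis)
}

# rebuild the minimal analysis object from the CSVs cli_analyze wrote
analysis_from_dir <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest_analyze.json"),
                                  simplifyVector = TRUE)
  cfg <- detection_config(
    threshold_sigma = manifest$threshold_sigma,
    consecutive_k = manifest$consecutive_k,
    training = c(manifest$analysis_start_year, manifest$release_start - 1),
    assessment = c(manifest$release_start, manifest$release_start + 50))
  res <- as_tibble(utils::read.csv(file.path(dir, "results.csv")))
  structure(
    list(results = res,
         replicates = as_tibble(utils::read.csv(file.path(dir, "replicates.csv"))),
         composites = as_tibble(utils::read.csv(file.path(dir, "composites.csv"))),
         cfg = cfg,
         analysis_start_year = manifest$analysis_start_year,
         release_start = manifest$release_start,
         metric_names = unique(res$metric_name),
         metrics = enumerate_metric_combinations()),
    class = "ews_analysis")
}

#' Evaluate analysis outputs into figure-analogue tables
#'
#' `mode = "summary"` writes per-metric/treatment strength, proportion and
#' consecutive-run tables; `mode = "roc"` writes the threshold sweep;
#' `mode = "training-sweep"` (which additionally needs the ensemble CSV)
#' writes the training-length table.
#'
#' @param analysis_dir Directory produced by [cli_analyze()].
#' @param mode One of `"summary"`, `"roc"`, `"training-sweep"`.
#' @param out_dir Output directory.
#' @param metric Metric for ROC / training sweep.
#' @param ensemble_csv Ensemble CSV (training sweep only).
#' @return Invisibly, the last table written.
#' @export
cli_evaluate <- function(analysis_dir, mode = c("summary", "roc",
                                                "training-sweep"),
                         out_dir = analysis_dir,
                         metric = "AR(1) + SD size", ensemble_csv = NULL) {
  mode <- match.arg(mode)
  t0 <- Sys.time()
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  analysis <- analysis_from_dir(analysis_dir)
  drop_lists <- function(df) df[, !vapply(df, is.list, logical(1)), drop = FALSE]
  if (mode == "summary") {
    s1 <- summarize_ensemble(analysis, "single")
    s2 <- summarize_ensemble(analysis, "consecutive")
    strength <- drop_lists(as.data.frame(s1[, c("metric_name", "treatment",
                                                "decline_rate", "n",
                                                "mean_max_strength",
                                                "se_max_strength")]))
    utils::write.csv(strength, file.path(out_dir, "fig4a_strength.csv"),
                     row.names = FALSE)
    props <- drop_lists(as.data.frame(dplyr::bind_rows(s1, s2)[,
      c("metric_name", "treatment", "decline_rate", "rule", "n",
        "n_detected", "prop_detected")]))
    utils::write.csv(props, file.path(out_dir, "fig4b_proportions.csv"),
                     row.names = FALSE)
    consec <- drop_lists(as.data.frame(s2[, c("metric_name", "treatment",
                                              "decline_rate", "n",
                                              "mean_max_run",
                                              "prop_detected")]))
    utils::write.csv(consec, file.path(out_dir, "fig5_consecutive.csv"),
                     row.names = FALSE)
    out <- props
    files <- c("fig4a_strength.csv", "fig4b_proportions.csv",
               "fig5_consecutive.csv")
  } else if (mode == "roc") {
    roc <- dplyr::bind_rows(roc_curve(analysis, metric, "single"),
                            roc_curve(analysis, metric, "consecutive"))
    utils::write.csv(as.data.frame(roc), file.path(out_dir, "fig7_roc.csv"),
                     row.names = FALSE)
    out <- roc
    files <- "fig7_roc.csv"
  } else {
    if (is.null(ensemble_csv)) {
      stop_invalid("training sweep requires `ensemble_csv`")
    }
    ens <- read_ensemble(ensemble_csv)
    sweep <- training_length_sweep(ens, metric = metric, cfg = analysis$cfg,
                                   release_start = analysis$release_start)
    utils::write.csv(as.data.frame(sweep),
                     file.path(out_dir, "fig6_training.csv"),
                     row.names = FALSE)
    out <- sweep
    files <- "fig6_training.csv"
  }
  manifest_write(out_dir, paste0("evaluate_", gsub("-", "_", mode)),
                 outputs = files, seed = NA,
                 extra = list(mode = mode, metric = metric),
                 elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(out)
}

#' Survey analysis from CSV inputs
#'
#' @param ssb_csv,sizes_csv Input CSVs (see [read_ssb()],
#'   [read_individual_sizes()]).
#' @param out_csv Output report path.
#' @param train_fraction,threshold_sigma,consecutive_k Analysis settings.
#' @param analysis_start_year First analysis year (default: first SSB
#'   year).
#' @param stock Stock label.
#' @return The [run_survey_ewsr()] object, invisibly.
#' @export
cli_survey <- function(ssb_csv, sizes_csv, out_csv = "survey_report.csv",
                       train_fraction = 0.5, threshold_sigma = 2,
                       consecutive_k = 2, analysis_start_year = NULL,
                       stock = "stock") {
  series <- survey_series(read_ssb(ssb_csv), read_individual_sizes(sizes_csv),
                          stock = stock,
                          analysis_start_year = analysis_start_year)
  res <- run_survey_ewsr(series, train_fraction = train_fraction,
                         threshold_sigma = threshold_sigma,
                         consecutive_k = consecutive_k)
  utils::write.csv(as.data.frame(res$report), out_csv, row.names = FALSE)
  invisible(res)
}
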