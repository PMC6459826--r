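#' Read individual body-size records and compute annual moments
#'
#' Expects a delimited table with columns `year` and `size` (one row per
#' measured individual, sizes positive). Rows from the same year are
#' pooled before computing the per-year sample mean and sample SD
#' (`n - 1`); years with fewer than two records carry a missing SD and are
#' flagged.
#'
#' @param path CSV file path.
#' @return A tibble with columns `year`, `mean_size`, `sd_size`,
#'   `n_records`, `flagged`.
#' @export
read_individual_sizes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop_invalid("size file `%s` is empty", path)
  if (!all(c("year", "size") %in% names(df))) {
    stop_invalid("size file must have columns `year` and `size`")
  }
  year <- suppressWarnings(as.numeric(df$year))
  size <- suppressWarnings(as.numeric(df$size))
  bad <- which(!is.finite(year) | !is.finite(size) | size <= 0)
  if (length(bad)) {
    stop_invalid("malformed size record at row %d of `%s` (year=%s, size=%s)",
                 bad[1], path, as.character(df$year[bad[1]]),
                 as.character(df$size[bad[1]]))
  }
  out <- tibble(year = year, size = size) |>
    dplyr::group_by(year) |>
    dplyr::summarise(mean_size = mean(size),
                     sd_size = if (dplyr::n() > 1) sd(size) else NA_real_,
                     n_records = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(year)
  out$flagged <- out$n_records < 2
  out
}

#' Read an annual spawning-stock-biomass table
#'
#' @param path CSV file with columns `year` and `ssb`.
#' @return A tibble with columns `year`, `ssb`, sorted by year.
#' @export
read_ssb <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop_invalid("SSB file `%s` is empty", path)
  if (!all(c("year", "ssb") %in% names(df))) {
    stop_invalid("SSB file must have columns `year` and `ssb`")
  }
  year <- suppressWarnings(as.numeric(df$year))
  ssb <- suppressWarnings(as.numeric(df$ssb))
  bad <- which(!is.finite(year) | !is.finite(ssb))
  if (length(bad)) {
    stop_invalid("malformed SSB record at row %d of `%s`", bad[1], path)
  }
  dplyr::arrange(tibble(year = year, ssb = ssb), year)
}

#' Assemble a survey series from SSB and size tables
#'
#' @param ssb Tibble from [read_ssb()].
#' @param sizes Tibble from [read_individual_sizes()].
#' @param stock Stock label.
#' @param analysis_start_year First year entering the analysis (e.g. the
#'   first year the stock was classed outside safe biological limits);
#'   defaults to the first SSB year.
#' @return A `survey_series` tibble with columns `year`, `ssb`,
#'   `mean_size`, `sd_size`, `n_records`.
#' @export
survey_series <- function(ssb, sizes, stock = "stock",
                          analysis_start_year = NULL) {
  stopifnot(is.data.frame(ssb), is.data.frame(sizes))
  if (is.unsorted(ssb$year, strictly = TRUE)) {
    stop_invalid("SSB years must be strictly increasing")
  }
  out <- dplyr::left_join(
    ssb, sizes[, c("year", "mean_size", "sd_size", "n_records")],
    by = "year")
  out <- as_tibble(out)
  attr(out, "stock") <- stock
  attr(out, "analysis_start_year") <- analysis_start_year %||% min(out$year)
  class(out) <- c("survey_series", class(out))
  out
}

#' Warning-signal analysis of a survey series
#'
#' Runs the composite-metric pipeline on a real-style survey series, with
#' SSB playing the biomass role for CV and AR(1). The first
#' `ceiling(train_fraction * n)` analysis years form the training window
#' (data included in the running baselines, signals disregarded); the
#' remainder is assessed for signals at `threshold_sigma`, under both the
#' single-year rule and the `consecutive_k`-consecutive-years rule.
#'
#' @param series A [survey_series()] object.
#' @param train_fraction Fraction of the analysis years used for training
#'   (default 0.5).
#' @param threshold_sigma Sigma threshold (default 2).
#' @param consecutive_k Consecutive-years requirement (default 2).
#' @param analysis_start_year Overrides the series attribute.
#' @return An object of class `survey_ewsr`: a list with `report` (one
#'   row per composite metric), `signals` (per-metric signal years,
#'   list), `composites` (tidy per-year values), the training and
#'   assessment years, and `n_metrics_consecutive`, the number of metrics
#'   with at least one consecutive-rule detection.
#' @export
run_survey_ewsr <- function(series, train_fraction = 0.5,
                            threshold_sigma = 2, consecutive_k = 2,
                            analysis_start_year = NULL) {
  stopifnot(is.data.frame(series))
  if (!is_scalar_number(train_fraction) || train_fraction <= 0 ||
      train_fraction >= 1) {
    stop_invalid("`train_fraction` must lie strictly between 0 and 1")
  }
  start <- analysis_start_year %||% attr(series, "analysis_start_year") %||%
    min(series$year)
  ssb_col <- if ("ssb" %in% names(series)) "ssb" else "biomass"
  df <- tibble(year = series$year, biomass = series[[ssb_col]],
               mean_size = series$mean_size, sd_size = series$sd_size)
  df <- df[df$year >= start & !is.na(df$biomass), , drop = FALSE]
  df <- df[order(df$year), , drop = FALSE]
  n <- nrow(df)
  if (n < 6) {
    stop_invalid("insufficient data: need at least 6 analysis years, got %d", n)
  }
  n_train <- ceiling(train_fraction * n)
  if (n_train >= n) stop_invalid("training split leaves no assessment years")
  training_years <- df$year[seq_len(n_train)]
  assessment_years <- df$year[(n_train + 1):n]
  window <- c(min(assessment_years), max(assessment_years))

  metrics <- enumerate_metric_combinations()
  cm <- replicate_composites(df, start, metrics)

  report <- vector("list", length(metrics))
  signals <- vector("list", length(metrics))
  comps <- vector("list", length(metrics))
  for (mi in seq_along(metrics)) {
    metric <- tibble(year = cm$years, value = cm$composites[[mi]])
    hit <- metric$year >= window[1] & metric$year <= window[2] &
      !is.na(metric$value) & metric$value > threshold_sigma
    sig <- sort(as.integer(metric$year[hit]))
    det <- consecutive_filter(sig, k = consecutive_k)
    signals[[mi]] <- list(single = sig, consecutive = det)
    comps[[mi]] <- tibble(metric_name = names(metrics)[mi],
                          year = metric$year, value = metric$value)
    report[[mi]] <- tibble(
      metric_name = names(metrics)[mi],
      n_signal_years = length(sig),
      first_signal_year = if (length(sig)) sig[1] else NA_integer_,
      n_consecutive_detections = length(det),
      first_consecutive_year = if (length(det)) det[1] else NA_integer_,
      max_strength = max_signal_strength(metric, window),
      includes_size = any(c("MEAN_SIZE", "SD_SIZE") %in% metrics[[mi]])
    )
  }
  report <- dplyr::bind_rows(report)
  names(signals) <- names(metrics)
  structure(
    list(report = report, signals = signals,
         composites = dplyr::bind_rows(comps),
         training_years = training_years,
         assessment_years = assessment_years,
         threshold_sigma = threshold_sigma, consecutive_k = consecutive_k,
         n_metrics_consecutive = sum(report$n_consecutive_detections > 0),
         stock = attr(series, "stock") %||% "stock"),
    class = "survey_ewsr"
  )
}

#' @export
print.survey_ewsr <- function(x, ...) {
  cat(sprintf(
    "<survey_ewsr> %s: training %d-%d, assessment %d-%d; %d/%d metrics with consecutive signals at %g sigma\n",
    x$stock, min(x$training_years), max(x$training_years),
    min(x$assessment_years), max(x$assessment_years),
    x$n_metrics_consecutive, nrow(x$report), x$threshold_sigma))
  invisible(x)
}

#' Generate synthetic survey fixture files
#'
#' Writes a pair of CSVs (annual SSB; individual sizes) emulating either a
#' stock recovering after a collapse (post-split upward shifts in SSB,
#' mean size and SD size) or a mean-stationary, noisy, non-recovering
#' stock. The fixtures are synthetic stand-ins for real survey extracts
#' and are fully determined by `seed`.
#'
#' @param kind `"recovering"` or `"not_recovering"`.
#' @param seed Integer seed.
#' @param dir Output directory.
#' @param n_individuals Size records per year.
#' @return A list with `ssb_path`, `sizes_path`, `kind`, and the first
#'   analysis year `analysis_start_year`.
#' @export
make_survey_fixture <- function(kind = c("recovering", "not_recovering"),
                                seed = 18, dir = tempdir(),
                                n_individuals = 60) {
  kind <- match.arg(kind)
  set.seed(as.integer(seed))
  if (kind == "recovering") {
    years <- 1989:2018
    n <- length(years)
    ramp <- rep(1, n)
    late <- years >= 2009
    ramp[late] <- 1 + 1.5 * (years[late] - 2009) / (2018 - 2009)
    ssb <- 60 * ramp * exp(rnorm(n, 0, 0.10))
    mu <- rep(450, n)
    mu[late] <- 450 + 450 * (years[late] - 2009) / (2018 - 2009)
    sl <- rep(0.35, n)
    sl[late] <- 0.35 + 0.22 * (years[late] - 2009) / (2018 - 2009)
  } else {
    years <- 2001:2020
    n <- length(years)
    ssb <- 25 * exp(rnorm(n, 0, 0.15))
    mu <- rep(400, n)
    sl <- rep(0.40, n)
  }
  sizes <- do.call(rbind, lapply(seq_along(years), function(i) {
    data.frame(year = years[i],
               size = round(rlnorm(n_individuals, log(mu[i]), sl[i]), 1))
  }))
  ssb_path <- file.path(dir, paste0(kind, "_ssb.csv"))
  sizes_path <- file.path(dir, paste0(kind, "_sizes.csv"))
  utils::write.csv(data.frame(year = years, ssb = round(ssb, 3)), ssb_path,
                   row.names = FALSE)
  utils::write.csv(sizes, sizes_path, row.names = FALSE)
  list(ssb_path = ssb_path, sizes_path = sizes_path, kind = kind,
       analysis_start_year = years[1])
}
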