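#' Run the full warning-signal analysis over an ensemble
#'
#' For every (treatment, replicate) series: computes the four raw
#' indicators from `analysis_start_year`, normalizes each against its
#' running baseline, sums every indicator subset into the composite
#' metrics, estimates the recovery year by the single-break
#' piecewise-constant fit, and records single-rule signal years and
#' consecutive-rule detections inside the replicate's assessment window
#' (release year to recovery year for release treatments; the config's
#' fixed assessment window for the control).
#'
#' @param ensemble Tidy ensemble tibble from [generate_ensemble()] (or
#'   [read_ensemble()]).
#' @param cfg A [detection_config()].
#' @param analysis_start_year First year of the indicator windows and
#'   running baselines (default 2010, the start of the collapse plateau).
#' @param release_start Year fishing pressure starts declining; start of
#'   every assessment window.
#' @param metrics Named list of indicator subsets, as
#'   [enumerate_metric_combinations()].
#' @param fit_start_year First year of the recovery-time fit window.
#' @param recovery_margin Relative margin for [recovery_time()].
#' @return An object of class `ews_analysis`: a list with tibbles
#'   `results` (one row per replicate x metric), `replicates` (one row per
#'   replicate with recovery year and assessment window), `composites`
#'   (per-year composite values), plus the configuration used.
#' @export
ews_analysis <- function(ensemble, cfg = detection_config(),
                         analysis_start_year = 2010, release_start = 2040,
                         metrics = enumerate_metric_combinations(),
                         fit_start_year = release_start,
                         recovery_margin = 0.5) {
  stopifnot(is.data.frame(ensemble))
  required <- c("treatment", "decline_rate", "replicate", "year", "biomass",
                "mean_size", "sd_size")
  missing_cols <- setdiff(required, names(ensemble))
  if (length(missing_cols)) {
    stop_invalid("ensemble lacks required column(s): %s",
                 paste(missing_cols, collapse = ", "))
  }
  if (nrow(ensemble) == 0) stop_invalid("ensemble is empty")

  key <- interaction(ensemble$treatment, ensemble$replicate, drop = TRUE)
  groups <- split(seq_len(nrow(ensemble)), key)
  metric_names <- names(metrics)

  rep_rows <- vector("list", length(groups))
  res_rows <- vector("list", length(groups))
  comp_rows <- vector("list", length(groups))

  for (gi in seq_along(groups)) {
    rows <- groups[[gi]]
    series <- ensemble[rows, , drop = FALSE]
    series <- series[order(series$year), , drop = FALSE]
    info <- replicate_detections(series, cfg, analysis_start_year,
                                 release_start, metrics, fit_start_year,
                                 recovery_margin)
    id <- tibble(treatment = series$treatment[1],
                 decline_rate = series$decline_rate[1],
                 replicate = series$replicate[1])
    rep_rows[[gi]] <- dplyr::bind_cols(id, info$replicate)
    res_rows[[gi]] <- dplyr::bind_cols(id[rep(1, nrow(info$results)), ],
                                       info$results)
    comp_rows[[gi]] <- dplyr::bind_cols(id[rep(1, nrow(info$composites)), ],
                                        info$composites)
  }

  structure(
    list(results = dplyr::bind_rows(res_rows),
         replicates = dplyr::bind_rows(rep_rows),
         composites = dplyr::bind_rows(comp_rows),
         cfg = cfg, analysis_start_year = analysis_start_year,
         release_start = release_start, metric_names = metric_names,
         metrics = metrics),
    class = "ews_analysis"
  )
}

# per-replicate pipeline shared with the survey module: indicators ->
# running normalization -> composites -> windowed detection
replicate_composites <- function(series, analysis_start_year, metrics) {
  ids <- sort(unique(unlist(metrics)))
  norm <- lapply(ids, function(id) {
    raw <- compute_indicator_series(series, id, analysis_start_year)
    normalize_running(raw)$value
  })
  names(norm) <- ids
  years <- series$year[series$year >= analysis_start_year]
  comp <- lapply(metrics, function(members) Reduce(`+`, norm[members]))
  list(years = sort(years), composites = comp, normalized = norm)
}

replicate_detections <- function(series, cfg, analysis_start_year,
                                 release_start, metrics, fit_start_year,
                                 recovery_margin) {
  cm <- replicate_composites(series, analysis_start_year, metrics)
  years <- cm$years
  is_control <- series$decline_rate[1] == 0
  recov <- recovery_time(series, fit_start_year = fit_start_year,
                         margin = recovery_margin)
  recovery_year <- as.integer(recov)
  window <- if (is_control) {
    cfg$assessment
  } else {
    c(release_start, if (is.na(recovery_year)) NA_integer_ else recovery_year)
  }
  recovered <- !is_control && !is.na(recovery_year)

  nres <- length(metrics)
  res <- tibble(
    metric_name = names(metrics),
    recovery_year = rep(recovery_year, nres),
    recovered = rep(recovered, nres),
    assess_start = rep(window[1], nres),
    assess_end = rep(window[2], nres),
    n_signals_single = NA_integer_, first_signal_single = NA_integer_,
    any_single = FALSE, first_detection_consecutive = NA_integer_,
    any_consecutive = FALSE, max_strength = NA_real_, max_run = NA_integer_
  )
  comp_long <- vector("list", nres)
  for (mi in seq_len(nres)) {
    vals <- cm$composites[[mi]]
    metric <- tibble(year = years, value = vals)
    comp_long[[mi]] <- tibble(metric_name = names(metrics)[mi],
                              year = years, value = vals)
    if (!is.na(window[2])) {
      sig <- detect_signals(metric, cfg, window = window)
      det <- consecutive_filter(sig, k = cfg$consecutive_k)
      res$n_signals_single[mi] <- length(sig)
      res$first_signal_single[mi] <- if (length(sig)) sig[1] else NA_integer_
      res$any_single[mi] <- length(sig) > 0
      res$first_detection_consecutive[mi] <-
        if (length(det)) det[1] else NA_integer_
      res$any_consecutive[mi] <- length(det) > 0
      res$max_strength[mi] <- max_signal_strength(metric, window)
      res$max_run[mi] <- max_consecutive_run(sig)
    }
  }
  list(
    replicate = tibble(recovery_year = recovery_year, recovered = recovered,
                       assess_start = window[1], assess_end = window[2]),
    results = res,
    composites = dplyr::bind_rows(comp_long)
  )
}

#' Classify replicate outcomes
#'
#' Release-treatment replicates are true positives (TP) when at least one
#' detection under the rule fell inside their assessment window, otherwise
#' false negatives (FN); control replicates with a detection are false
#' positives (FP), otherwise true negatives (TN).
#'
#' @param result One or more rows of an `ews_analysis` `results` tibble.
#' @param rule `"single"` or `"consecutive"`.
#' @return Character vector of outcomes in `c("TP", "FN", "FP", "TN")`.
#' @export
classify_replicate <- function(result, rule = c("single", "consecutive")) {
  rule <- match.arg(rule)
  detected <- if (rule == "single") result$any_single else
    result$any_consecutive
  is_control <- result$decline_rate == 0
  ifelse(is_control,
         ifelse(detected, "FP", "TN"),
         ifelse(detected, "TP", "FN"))
}

#' Summarize detection performance per metric and treatment
#'
#' Proportion of replicates flagged under the rule, mean and standard
#' error (sample SD over replicates divided by sqrt(n)) of the maximum
#' signal strength, mean longest consecutive-signal run, and lead times
#' (recovery year minus the year of the first qualifying detection).
#' Release-treatment replicates that the margin rule classed as not
#' recovered are excluded from the denominators (their count is reported
#' in the `n_excluded` attribute).
#'
#' @param analysis An [ews_analysis()] object.
#' @param rule `"single"` or `"consecutive"`.
#' @return A tibble with one row per (metric, treatment) and a `lead_times`
#'   list column.
#' @export
summarize_ensemble <- function(analysis, rule = c("single", "consecutive")) {
  rule <- match.arg(rule)
  res <- analysis$results
  excluded <- res$decline_rate != 0 & !res$recovered
  res <- res[!excluded, , drop = FALSE]
  res$detected <- if (rule == "single") res$any_single else
    res$any_consecutive
  res$first_det <- if (rule == "single") res$first_signal_single else
    res$first_detection_consecutive

  out <- res |>
    dplyr::group_by(.data$metric_name, .data$treatment, .data$decline_rate) |>
    dplyr::summarise(
      rule = rule,
      n = dplyr::n(),
      n_detected = sum(.data$detected),
      prop_detected = mean(.data$detected),
      mean_max_strength = mean(.data$max_strength, na.rm = TRUE),
      se_max_strength = sd(.data$max_strength, na.rm = TRUE) /
        sqrt(sum(!is.na(.data$max_strength))),
      mean_max_run = mean(.data$max_run, na.rm = TRUE),
      lead_times = list(.data$recovery_year[.data$detected] -
                          .data$first_det[.data$detected]),
      mean_lead = mean(.data$recovery_year[.data$detected] -
                         .data$first_det[.data$detected]),
      .groups = "drop"
    )
  attr(out, "n_excluded") <- sum(excluded) / length(analysis$metric_names)
  out
}

# per-replicate detection statistics for re-thresholding: the single-rule
# statistic is the window maximum; the consecutive-rule statistic is the
# largest over adjacent-year pairs of the pairwise minimum, so that
# "detected at threshold theta" is exactly "statistic > theta"
replicate_threshold_stats <- function(analysis, metric) {
  comp <- analysis$composites
  comp <- comp[comp$metric_name == metric, , drop = FALSE]
  if (nrow(comp) == 0) {
    stop_invalid("metric %s not present in the analysis", metric)
  }
  wins <- analysis$replicates
  key <- paste(comp$treatment, comp$replicate)
  groups <- split(seq_len(nrow(comp)), key)
  wkey <- paste(wins$treatment, wins$replicate)

  out <- wins[, c("treatment", "decline_rate", "replicate", "recovered")]
  out$stat_single <- NA_real_
  out$stat_consecutive <- NA_real_
  for (i in seq_len(nrow(wins))) {
    rows <- groups[[wkey[i]]]
    if (is.na(wins$assess_end[i])) next
    yy <- comp$year[rows]
    vv <- comp$value[rows]
    keep <- yy >= wins$assess_start[i] & yy <= wins$assess_end[i] & !is.na(vv)
    yy <- yy[keep]
    vv <- vv[keep]
    if (!length(vv)) next
    o <- order(yy)
    yy <- yy[o]
    vv <- vv[o]
    out$stat_single[i] <- max(vv)
    adj <- which(diff(yy) == 1L)
    if (length(adj)) {
      out$stat_consecutive[i] <- max(pmin(vv[adj], vv[adj + 1L]))
    } else {
      out$stat_consecutive[i] <- -Inf
    }
  }
  out
}

#' Receiver operating characteristic of one composite metric
#'
#' Reclassifies every replicate over a grid of sigma thresholds. The true
#' positive rate pools all release treatments (recovered replicates); the
#' false positive rate is the control proportion. The 2-sigma point is
#' always included in the grid.
#'
#' @param analysis An [ews_analysis()] object containing control and
#'   release treatments.
#' @param metric Metric display name (default the headline
#'   `"AR(1) + SD size"`).
#' @param rule `"single"` or `"consecutive"`.
#' @param thresholds Sigma thresholds; default a grid from 0.01 to 6.
#' @return A tibble with columns `metric_name`, `rule`, `threshold`,
#'   `fpr`, `tpr`, `n_positive`, `n_negative`.
#' @export
roc_curve <- function(analysis, metric = "AR(1) + SD size",
                      rule = c("single", "consecutive"), thresholds = NULL) {
  rule <- match.arg(rule)
  thresholds <- sort(unique(thresholds %||%
                              c(seq(0.01, 6, length.out = 120), 2)))
  stats <- replicate_threshold_stats(analysis, metric)
  pos <- stats[stats$decline_rate != 0 & stats$recovered, , drop = FALSE]
  neg <- stats[stats$decline_rate == 0, , drop = FALSE]
  if (nrow(neg) == 0) {
    stop_invalid("ROC requires a control treatment in the ensemble")
  }
  if (nrow(pos) == 0) {
    stop_invalid("ROC requires recovered release-treatment replicates")
  }
  stat_col <- if (rule == "single") "stat_single" else "stat_consecutive"
  spos <- pos[[stat_col]]
  sneg <- neg[[stat_col]]
  tpr <- vapply(thresholds, function(th) mean(spos > th, na.rm = TRUE),
                numeric(1))
  fpr <- vapply(thresholds, function(th) mean(sneg > th, na.rm = TRUE),
                numeric(1))
  tibble(metric_name = metric, rule = rule, threshold = thresholds,
         fpr = fpr, tpr = tpr, n_positive = nrow(pos), n_negative = nrow(neg))
}

#' Sensitivity of detection performance to training length
#'
#' Re-runs the indicator, normalization and detection pipeline for one
#' metric with the analysis start year set so that exactly `L` training
#' years precede the release year, for each `L` in `lengths`. Recovery
#' years are estimated once (they do not depend on the training window).
#'
#' @inheritParams ews_analysis
#' @param metric Metric display name.
#' @param lengths Integer vector of training lengths in years (default
#'   2 to 30).
#' @return A tibble with one row per (length, rule): columns `length`,
#'   `rule`, `tp_prop` (pooled over recovered release replicates) and
#'   `fp_prop` (control).
#' @export
training_length_sweep <- function(ensemble, metric = "AR(1) + SD size",
                                  lengths = 2:30, cfg = detection_config(),
                                  release_start = 2040,
                                  fit_start_year = release_start,
                                  recovery_margin = 0.5) {
  if (any(lengths < 2)) {
    stop_invalid("training lengths below 2 years cannot support a signal")
  }
  all_metrics <- enumerate_metric_combinations()
  if (!metric %in% names(all_metrics)) {
    stop_invalid("unknown metric name: %s", metric)
  }
  metrics <- all_metrics[metric]

  rows <- list()
  for (L in sort(unique(as.integer(lengths)))) {
    start <- release_start - L
    cfgL <- detection_config(threshold_sigma = cfg$threshold_sigma,
                             consecutive_k = cfg$consecutive_k,
                             training = c(start, release_start - 1),
                             assessment = cfg$assessment)
    an <- ews_analysis(ensemble, cfg = cfgL, analysis_start_year = start,
                       release_start = release_start, metrics = metrics,
                       fit_start_year = fit_start_year,
                       recovery_margin = recovery_margin)
    res <- an$results
    pos <- res[res$decline_rate != 0 & res$recovered, , drop = FALSE]
    neg <- res[res$decline_rate == 0, , drop = FALSE]
    for (rule in c("single", "consecutive")) {
      det_pos <- if (rule == "single") pos$any_single else pos$any_consecutive
      det_neg <- if (rule == "single") neg$any_single else neg$any_consecutive
      rows[[length(rows) + 1]] <- tibble(
        length = L, rule = rule,
        tp_prop = if (nrow(pos)) mean(det_pos) else NA_real_,
        fp_prop = if (nrow(neg)) mean(det_neg) else NA_real_)
    }
  }
  dplyr::bind_rows(rows)
}

#' @export
print.ews_analysis <- function(x, ...) {
  cat(sprintf(
    "<ews_analysis> %d replicates x %d metrics (analysis from %d, release %d)\n",
    nrow(x$replicates), length(x$metric_names), x$analysis_start_year,
    x$release_start))
  invisible(x)
}
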