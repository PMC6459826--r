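#' Normalize a series against its running baseline
#'
#' Converts a raw indicator series `w_t` into the running z-score
#' `(w_t - mean(w[1:t])) / sd(w[1:t])`, where the running mean and sample
#' standard deviation include the current observation and start at the
#' first defined value of the series. The score is defined from the second
#' value onward; positions where the running SD is zero return 0 (flagged
#' via the `degenerate` attribute). Leading or interior missing values are
#' skipped: running statistics accumulate over observed values only, and
#' missing positions stay missing.
#'
#' @param x Either a numeric vector or an indicator tibble with columns
#'   `year` and `value` (as returned by [compute_indicator_series()]).
#' @return Same shape as the input with values replaced by running
#'   z-scores; attribute `degenerate` marks positions (or years) where the
#'   running SD was zero.
#' @examples
#' normalize_running(c(1, 2, 3)) # NA, 0.7071, 1
#' @export
normalize_running <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("year", "value") %in% names(x)))
    z <- running_zscore(x$value)
    out <- x
    out$value <- as.numeric(z)
    deg <- attr(z, "degenerate")
    if (length(deg)) attr(out, "degenerate") <- x$year[deg]
    return(out)
  }
  running_zscore(x)
}

running_zscore <- function(x) {
  out <- rep(NA_real_, length(x))
  idx <- which(!is.na(x))
  if (length(idx) < 2) {
    return(structure(out, degenerate = integer(0)))
  }
  v <- x[idx]
  n <- length(v)
  t_idx <- seq_len(n)
  m <- cumsum(v) / t_idx
  c0 <- v - mean(v)
  s1 <- cumsum(c0)
  s2 <- cumsum(c0^2)
  varv <- (s2 - s1^2 / t_idx) / (t_idx - 1)
  varv[varv < 0] <- 0
  sdv <- sqrt(varv)
  scale <- cummax(abs(v)) + abs(m)
  z <- rep(NA_real_, n)
  degenerate <- logical(n)
  for (t in 2:n) {
    if (sdv[t] <= 1e-12 * max(scale[t], 1e-300)) {
      z[t] <- 0
      degenerate[t] <- TRUE
    } else {
      z[t] <- (v[t] - m[t]) / sdv[t]
    }
  }
  out[idx] <- z
  structure(out, degenerate = idx[degenerate])
}

#' Enumerate all composite-metric indicator subsets
#'
#' Every non-empty subset of the supplied indicator ids, ordered by subset
#' size and then lexicographically; four indicators give the 15 composite
#' metrics.
#'
#' @param indicator_ids Character vector of 1-4 distinct indicator ids.
#' @return A named list of character vectors; names are the display metric
#'   names (e.g. `"AR(1) + SD size"`).
#' @export
enumerate_metric_combinations <- function(indicator_ids = ews_indicators()) {
  if (length(indicator_ids) == 0) {
    stop_invalid("`indicator_ids` must be non-empty")
  }
  ids <- sort(unique(as.character(indicator_ids)))
  if (length(ids) != length(indicator_ids)) {
    stop_invalid("`indicator_ids` must be distinct")
  }
  subsets <- list()
  for (k in seq_along(ids)) {
    cmb <- utils::combn(ids, k, simplify = FALSE)
    subsets <- c(subsets, cmb)
  }
  names(subsets) <- vapply(subsets, metric_name, character(1))
  subsets
}

#' Display name of a composite metric
#'
#' @param indicator_ids Character vector of indicator ids.
#' @return A string such as `"AR(1) + SD size"`.
#' @export
metric_name <- function(indicator_ids) {
  ids <- sort(as.character(indicator_ids))
  unknown <- setdiff(ids, names(indicator_display))
  if (length(unknown)) {
    stop_invalid("unknown indicator id(s): %s", paste(unknown, collapse = ", "))
  }
  paste(indicator_display[ids], collapse = " + ")
}

#' Sum normalized indicator series into a composite metric
#'
#' @param members A list of normalized indicator tibbles (columns `year`,
#'   `value`) sharing an identical year axis. A missing member value makes
#'   the composite missing for that year.
#' @param name Optional metric name; derived from member `indicator_id`
#'   columns when present.
#' @return A tibble with columns `metric_name`, `year`, `value`.
#' @export
composite_metric <- function(members, name = NULL) {
  if (is.data.frame(members)) members <- list(members)
  if (length(members) == 0) stop_invalid("`members` must be non-empty")
  years <- members[[1]]$year
  for (m in members) {
    if (!identical(as.numeric(m$year), as.numeric(years))) {
      stop_invalid("member series do not share the same year axis")
    }
  }
  value <- Reduce(`+`, lapply(members, function(m) m$value))
  if (is.null(name)) {
    ids <- vapply(members, function(m) m$indicator_id[1], character(1))
    name <- if (anyNA(ids)) "composite" else metric_name(ids)
  }
  tibble(metric_name = name, year = years, value = value)
}

#' Detection configuration
#'
#' @param threshold_sigma Sigma threshold above which a composite value is
#'   a warning signal (default 2).
#' @param consecutive_k Number of consecutive signal years required by the
#'   consecutive rule (default 2).
#' @param training Length-2 integer vector: first and last year of the
#'   training window, whose data feed the running baselines but whose
#'   signals are disregarded.
#' @param assessment Length-2 integer vector: first and last year of the
#'   assessment window scanned for signals (for the control treatment; for
#'   recovery treatments the window ends at each replicate's recovery
#'   year).
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(threshold_sigma = 2, consecutive_k = 2,
                             training = c(2010, 2039),
                             assessment = c(2040, 2090)) {
  if (!is_scalar_number(threshold_sigma) || threshold_sigma <= 0) {
    stop_invalid("`threshold_sigma` must be > 0")
  }
  if (!is_scalar_number(consecutive_k) || consecutive_k < 1 ||
      consecutive_k != round(consecutive_k)) {
    stop_invalid("`consecutive_k` must be a positive integer")
  }
  training <- as.integer(training)
  assessment <- as.integer(assessment)
  if (length(training) != 2 || length(assessment) != 2 ||
      training[1] > training[2] || assessment[1] > assessment[2]) {
    stop_invalid("`training` and `assessment` must each be ordered year pairs")
  }
  if (training[2] >= assessment[1]) {
    stop_invalid("training window must end before the assessment window starts")
  }
  structure(list(threshold_sigma = threshold_sigma,
                 consecutive_k = as.integer(consecutive_k),
                 training = training, assessment = assessment),
            class = "detection_config")
}

#' Years with a warning signal
#'
#' Returns the assessment-window years whose composite value exceeds the
#' sigma threshold. Training-window exceedances are excluded from the
#' result (although training data participated in all running statistics).
#'
#' @param metric A composite tibble (columns `year`, `value`).
#' @param cfg A [detection_config()].
#' @param window Optional length-2 year vector overriding the config's
#'   assessment window (used when the window ends at a replicate-specific
#'   recovery year).
#' @return Sorted integer vector of signal years.
#' @export
detect_signals <- function(metric, cfg = detection_config(), window = NULL) {
  stopifnot(is.data.frame(metric), all(c("year", "value") %in% names(metric)))
  win <- window %||% cfg$assessment
  in_win <- metric$year >= win[1] & metric$year <= win[2]
  if (!any(in_win)) {
    warning("assessment window contains no metric years; no signals assessed")
    return(integer(0))
  }
  hit <- in_win & !is.na(metric$value) & metric$value > cfg$threshold_sigma
  sort(as.integer(metric$year[hit]))
}

#' Keep only years ending a run of k consecutive signal years
#'
#' @param signal_years Integer vector of signal years.
#' @param k Required run length; `k = 1` is the identity.
#' @return Sorted integer vector of detection years `y` such that
#'   `y, y-1, ..., y-k+1` are all signal years.
#' @export
consecutive_filter <- function(signal_years, k = 2) {
  if (!is_scalar_number(k) || k < 1 || k != round(k)) {
    stop_invalid("`k` must be a positive integer")
  }
  ys <- sort(unique(as.integer(signal_years)))
  if (k == 1 || length(ys) == 0) return(ys)
  keep <- vapply(ys, function(y) all((y - k + 1):y %in% ys), logical(1))
  ys[keep]
}

#' Maximum composite strength over a window
#'
#' @param metric A composite tibble (columns `year`, `value`).
#' @param window Length-2 year vector.
#' @return The maximum composite value in the window (missing values
#'   skipped); `NA` if every value in the window is missing.
#' @export
max_signal_strength <- function(metric, window) {
  stopifnot(length(window) == 2, window[1] <= window[2])
  v <- metric$value[metric$year >= window[1] & metric$year <= window[2]]
  v <- v[!is.na(v)]
  if (length(v) == 0) return(NA_real_)
  max(v)
}

#' Longest run of consecutive signal years
#'
#' @param signal_years Integer vector of signal years.
#' @return Length of the longest run of consecutive years; 0 if empty.
#' @export
max_consecutive_run <- function(signal_years) {
  ys <- sort(unique(as.integer(signal_years)))
  if (length(ys) == 0) return(0L)
  # lengths of maximal blocks of consecutive years
  as.integer(max(tapply(ys, cumsum(c(1L, diff(ys) != 1L)), length)))
}
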