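#' Indicator identifiers
#'
#' The four stability indicators: lag-1 autoregressive coefficient and
#' coefficient of variation of biomass (abundance-based), and the mean and
#' standard deviation of individual body size (trait-based).
#'
#' @return Character vector of indicator ids.
#' @export
ews_indicators <- function() c("AR1", "CV", "MEAN_SIZE", "SD_SIZE")

indicator_display <- c(AR1 = "AR(1)", CV = "CV", MEAN_SIZE = "mean size",
                       SD_SIZE = "SD size")

#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean.
#'
#' @param x Numeric vector, length at least 2.
#' @return A single number; always >= 0 for positive-valued series.
#' @examples
#' coefficient_of_variation(c(2, 4)) # sqrt(2)/3
#' @export
coefficient_of_variation <- function(x) {
  if (!is.numeric(x) || length(x) < 2) {
    stop_invalid("insufficient data: CV needs at least 2 values")
  }
  m <- mean(x)
  if (m == 0) stop_invalid("CV undefined: mean of the series is zero")
  sd(x) / m
}

#' Lag-1 autoregressive coefficient
#'
#' Slope of the ordinary-least-squares regression (with intercept) of
#' `x[t]` on `x[t-1]`, i.e. the conditional-least-squares AR(1) estimate.
#' The estimate is not clamped to `[-1, 1]`. A window with zero predictor
#' variance returns 0 with attribute `degenerate = TRUE`.
#'
#' @param x Numeric vector, length at least 3.
#' @return A single number, with attribute `degenerate` when the predictor
#'   is constant.
#' @examples
#' ar1_coefficient(c(1, 2, 1, 2, 1)) # -1
#' @export
ar1_coefficient <- function(x) {
  if (!is.numeric(x) || length(x) < 3) {
    stop_invalid("insufficient data: AR(1) needs at least 3 values")
  }
  n <- length(x)
  xlag <- x[-n]
  xlead <- x[-1]
  mlag <- mean(xlag)
  v <- sum((xlag - mlag)^2)
  scale2 <- mean(xlag^2)
  if (v <= 1e-24 * max(scale2, 1e-300)) {
    return(structure(0, degenerate = TRUE))
  }
  cv <- sum((xlag - mlag) * (xlead - mean(xlead)))
  cv / v
}

# Expanding-window CV over x[1..t] for every t; NA where undefined (t < 2
# or zero mean). Centered cumulative sums keep the variance numerically
# stable for large-magnitude biomass series.
expanding_cv <- function(x) {
  n <- length(x)
  out <- rep(NA_real_, n)
  if (n < 2) return(out)
  t_idx <- seq_len(n)
  m <- cumsum(x) / t_idx
  c0 <- x - mean(x)
  s1 <- cumsum(c0)
  s2 <- cumsum(c0^2)
  varx <- (s2 - s1^2 / t_idx) / (t_idx - 1)
  varx[varx < 0] <- 0
  ok <- t_idx >= 2 & m != 0
  out[ok] <- sqrt(varx[ok]) / m[ok]
  out
}

# Expanding-window OLS AR(1) slope over x[1..t]; NA for t < 3; 0 where the
# lagged predictor has (numerically) zero variance.
expanding_ar1 <- function(x) {
  n <- length(x)
  out <- rep(NA_real_, n)
  if (n < 3) return(out)
  c0 <- x - mean(x)
  s1 <- cumsum(c0)
  s2 <- cumsum(c0^2)
  cross <- cumsum(c0[-n] * c0[-1])
  scale2 <- mean(x^2)
  for (t in 3:n) {
    m <- t - 1                      # number of lag pairs
    sum_lag <- s1[t - 1]
    sum_lead <- s1[t] - c0[1]
    v <- s2[t - 1] - sum_lag^2 / m
    if (v <= 1e-24 * max(scale2, 1e-300)) {
      out[t] <- 0
    } else {
      cv <- cross[t - 1] - sum_lag * sum_lead / m
      out[t] <- cv / v
    }
  }
  out
}

rolling_stat <- function(x, k, fun) {
  n <- length(x)
  out <- rep(NA_real_, n)
  if (n < k) return(out)
  for (t in k:n) out[t] <- fun(x[(t - k + 1):t])
  out
}

#' Compute one raw indicator series from an annual series
#'
#' CV and AR(1) are computed on the biomass column over a window running
#' from `analysis_start_year` up to and including year `t` (the default
#' expanding scheme; a fixed-width rolling window is available via
#' `window_scheme = "rolling"`). The trait indicators are the year-`t`
#' observations of mean and SD body size. Years where an indicator is not
#' yet defined (the first year for CV, the first two for AR(1)) carry `NA`,
#' so every indicator shares the same year axis.
#'
#' @param series An `annual_series` tibble (or any data frame with columns
#'   `year`, `biomass`, `mean_size`, `sd_size`).
#' @param indicator_id One of [ews_indicators()].
#' @param analysis_start_year First year of the analysis window.
#' @param window_scheme `"expanding"` (default) or `"rolling"`.
#' @param rolling_k Window width in years when `window_scheme = "rolling"`.
#' @return A tibble with columns `indicator_id`, `year`, `value`.
#' @export
compute_indicator_series <- function(series, indicator_id,
                                     analysis_start_year,
                                     window_scheme = c("expanding", "rolling"),
                                     rolling_k = NULL) {
  window_scheme <- match.arg(window_scheme)
  indicator_id <- match.arg(indicator_id, ews_indicators())
  stopifnot(is.data.frame(series),
            all(c("year", "biomass") %in% names(series)))
  sub <- series[series$year >= analysis_start_year, , drop = FALSE]
  sub <- sub[order(sub$year), , drop = FALSE]
  if (nrow(sub) == 0) {
    stop_invalid("series does not cover analysis_start_year = %d",
                 analysis_start_year)
  }
  value <- switch(
    indicator_id,
    CV = if (window_scheme == "expanding") {
      expanding_cv(sub$biomass)
    } else {
      rolling_stat(sub$biomass, rolling_k, coefficient_of_variation)
    },
    AR1 = if (window_scheme == "expanding") {
      expanding_ar1(sub$biomass)
    } else {
      rolling_stat(sub$biomass, rolling_k, function(z) {
        as.numeric(ar1_coefficient(z))
      })
    },
    MEAN_SIZE = sub$mean_size,
    SD_SIZE = sub$sd_size
  )
  tibble(indicator_id = indicator_id, year = sub$year, value = value)
}
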