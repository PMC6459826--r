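#' Fit a piecewise-constant model with a single break point
#'
#' Exhaustively searches every admissible break position (each segment at
#' least `min_segment` points), fits each segment by its mean, and returns
#' the global minimizer of the residual sum of squares. Ties are broken in
#' favour of the earliest break and flagged.
#'
#' @param y Numeric series, length at least `2 * min_segment`.
#' @param min_segment Minimum points per segment (default 2).
#' @return An object of class `breakpoint_fit`: a list with
#'   `break_index` (1-based index of the first point of the second
#'   segment), `seg1_mean`, `seg2_mean`, `sse`, `tie` (logical),
#'   `candidates` (the admissible last-index-of-first-segment values),
#'   `n` and `min_segment`.
#' @examples
#' fit_piecewise_constant(c(1, 1, 1, 5, 5, 5))
#' @export
fit_piecewise_constant <- function(y, min_segment = 2) {
  if (!is_scalar_number(min_segment) || min_segment < 1 ||
      min_segment != round(min_segment)) {
    stop_invalid("`min_segment` must be a positive integer")
  }
  if (!is.numeric(y) || anyNA(y)) {
    stop_invalid("`y` must be a numeric series without missing values")
  }
  n <- length(y)
  if (n < 2 * min_segment) {
    stop_invalid("insufficient data: need at least %d points, got %d",
                 2 * min_segment, n)
  }
  # centered cumulative sums: SSE is shift-invariant and this keeps the
  # arithmetic stable for large-magnitude biomass values
  c0 <- y - mean(y)
  s1 <- cumsum(c0)
  s2 <- cumsum(c0^2)
  ks <- min_segment:(n - min_segment)        # last index of first segment
  sse1 <- s2[ks] - s1[ks]^2 / ks
  sse2 <- (s2[n] - s2[ks]) - (s1[n] - s1[ks])^2 / (n - ks)
  sse <- sse1 + sse2
  best <- which.min(sse)                     # earliest on exact ties
  tol <- 1e-9 * max(s2[n], 1)
  tie <- sum(sse <= sse[best] + tol) > 1
  k <- ks[best]
  structure(
    list(break_index = k + 1L,
         seg1_mean = mean(y[1:k]),
         seg2_mean = mean(y[(k + 1):n]),
         sse = max(sse[best], 0),
         tie = tie,
         candidates = ks,
         n = n,
         min_segment = as.integer(min_segment)),
    class = "breakpoint_fit"
  )
}

#' @export
print.breakpoint_fit <- function(x, ...) {
  cat(sprintf(
    "<breakpoint_fit> break at index %d of %d: means %.4g -> %.4g, SSE %.4g%s\n",
    x$break_index, x$n, x$seg1_mean, x$seg2_mean, x$sse,
    if (x$tie) " (tied; earliest kept)" else ""))
  invisible(x)
}

#' Estimate the recovery year of a replicate
#'
#' Fits the single-break piecewise-constant model to the biomass series
#' from `fit_start_year` (the release year by default) to the series end.
#' The recovery year is the first year of the post-break segment, provided
#' the post-break mean exceeds the pre-break mean by the relative `margin`;
#' otherwise the replicate is classed as not recovered (`NA`). The margin
#' rule only classifies ambiguous series: evaluation of detection
#' performance uses treatment labels, not this rule. The default margin of
#' 50% separates genuine release recoveries (typically 3-10 fold biomass
#' increases) from the slow drift of a persistently fished stock.
#'
#' @param series An `annual_series` (or data frame with `year`, `biomass`).
#' @param fit_start_year First year of the fit window.
#' @param margin Required relative increase of the second-segment mean over
#'   the first (default 0.5).
#' @param min_segment Passed to [fit_piecewise_constant()].
#' @return The recovery year (integer) or `NA_integer_`, with the
#'   underlying fit in attribute `fit`.
#' @export
recovery_time <- function(series, fit_start_year = 2040, margin = 0.5,
                          min_segment = 2) {
  stopifnot(is.data.frame(series),
            all(c("year", "biomass") %in% names(series)))
  sub <- series[series$year >= fit_start_year, , drop = FALSE]
  sub <- sub[order(sub$year), , drop = FALSE]
  if (nrow(sub) < 2 * min_segment) {
    stop_invalid("series does not cover fit_start_year = %d with enough years",
                 fit_start_year)
  }
  fit <- fit_piecewise_constant(sub$biomass, min_segment = min_segment)
  recovered <- fit$seg2_mean > fit$seg1_mean * (1 + margin)
  year <- if (recovered) as.integer(sub$year[fit$break_index]) else NA_integer_
  structure(year, fit = fit)
}
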