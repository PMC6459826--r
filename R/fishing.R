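#' Default calendar phases of the collapse-and-release experiment
#'
#' Burn-in starts in 1667; recorded-era fishing ramps up from 1967; the
#' collapse plateau holds fishing constant from 2010; release (if any)
#' begins in 2040; simulations end in 2200.
#'
#' @return A named list of calendar years.
#' @export
default_phase_years <- function() {
  list(burn_in_start = 1667L, historic_start = 1967L, plateau_start = 2010L,
       release_start = 2040L, end_year = 2200L)
}

#' Construct a fishing-mortality schedule
#'
#' Maps calendar year to fishing mortality `F` (per year) through four
#' phases: zero during burn-in; a linear ramp from
#' `historic_start_fraction * plateau_F` to `plateau_F` across the historic
#' period; constant `plateau_F` through the collapse plateau; and, from the
#' release year, either constant `plateau_F` (control, `decline_rate = 0`)
#' or a linear decline removing `decline_rate` of the plateau level per
#' year, `F(t) = plateau_F * max(0, 1 - decline_rate * (t - release_start))`,
#' which reaches exactly zero after `ceiling(1/decline_rate)` years and
#' stays there.
#'
#' @param plateau_F Fishing mortality per year held during the collapse
#'   plateau (and, for the control, forever after).
#' @param decline_rate Fraction of `plateau_F` removed per year after the
#'   release year; in `[0, 1]`, with 0 meaning no release.
#' @param years Named list of phase boundary years, as
#'   [default_phase_years()].
#' @param historic_start_fraction Fraction of `plateau_F` applied in the
#'   first historic year.
#' @param historic_peak_fraction Multiple of `plateau_F` reached at
#'   `historic_peak_year`. Values above 1 emulate the recorded pattern of
#'   fishing mortality peaking and then being partially reduced before the
#'   plateau, which leaves the stock below its plateau equilibrium when the
#'   collapse period starts. 1 gives a plain monotone ramp.
#' @param historic_peak_year Calendar year of the historic peak.
#'
#' @return An object of class `fishing_schedule`.
#' @seealso [schedule_F()] to evaluate the schedule.
#' @export
make_fishing_schedule <- function(plateau_F = 1.0, decline_rate = 0,
                                  years = default_phase_years(),
                                  historic_start_fraction = 0.25,
                                  historic_peak_fraction = 1,
                                  historic_peak_year = 2000) {
  if (!is_scalar_number(plateau_F) || plateau_F < 0) {
    stop_invalid("`plateau_F` must be a single non-negative number")
  }
  if (!is_scalar_number(decline_rate) || decline_rate < 0 || decline_rate > 1) {
    stop_invalid("`decline_rate` must lie in [0, 1] (got %s)",
                 deparse(decline_rate))
  }
  needed <- c("burn_in_start", "historic_start", "plateau_start",
              "release_start", "end_year")
  if (!all(needed %in% names(years))) {
    stop_invalid("`years` must name %s", paste(needed, collapse = ", "))
  }
  yr <- lapply(years[needed], as.integer)
  if (is.unsorted(unlist(yr), strictly = TRUE)) {
    stop_invalid("phase boundary years must be strictly increasing")
  }
  if (!is_scalar_number(historic_start_fraction) ||
      historic_start_fraction < 0 || historic_start_fraction > 1) {
    stop_invalid("`historic_start_fraction` must lie in [0, 1]")
  }
  if (!is_scalar_number(historic_peak_fraction) || historic_peak_fraction < 1) {
    stop_invalid("`historic_peak_fraction` must be >= 1")
  }
  if (historic_peak_fraction > 1 &&
      (historic_peak_year <= yr$historic_start ||
         historic_peak_year > yr$plateau_start)) {
    stop_invalid("`historic_peak_year` must fall inside the historic phase")
  }
  structure(
    list(plateau_F = plateau_F, decline_rate = decline_rate, years = yr,
         historic_start_fraction = historic_start_fraction,
         historic_peak_fraction = historic_peak_fraction,
         historic_peak_year = as.integer(historic_peak_year)),
    class = "fishing_schedule"
  )
}

#' Fishing mortality at given calendar years
#'
#' @param schedule A [make_fishing_schedule()] object.
#' @param year Integer vector of calendar years.
#' @return Numeric vector of fishing mortality per year, same length as
#'   `year`.
#' @examples
#' s <- make_fishing_schedule(plateau_F = 0.8, decline_rate = 0.10)
#' schedule_F(s, c(2040, 2045, 2050, 2051))
#' @export
schedule_F <- function(schedule, year) {
  stopifnot(inherits(schedule, "fishing_schedule"))
  yr <- schedule$years
  pF <- schedule$plateau_F
  frac <- schedule$historic_start_fraction
  f <- numeric(length(year))

  hist <- year >= yr$historic_start & year < yr$plateau_start
  if (any(hist)) {
    peak <- schedule$historic_peak_fraction %||% 1
    if (peak > 1) {
      py <- schedule$historic_peak_year
      yh <- year[hist]
      up <- yh <= py
      fh <- numeric(length(yh))
      fh[up] <- pF * (frac + (peak - frac) *
                        (yh[up] - yr$historic_start) /
                        (py - yr$historic_start))
      fh[!up] <- pF * (peak - (peak - 1) *
                         (yh[!up] - py) / (yr$plateau_start - py))
      f[hist] <- fh
    } else {
      prog <- (year[hist] - yr$historic_start) /
        (yr$plateau_start - yr$historic_start)
      f[hist] <- pF * (frac + (1 - frac) * prog)
    }
  }

  plateau <- year >= yr$plateau_start & year < yr$release_start
  f[plateau] <- pF

  post <- year >= yr$release_start
  if (any(post)) {
    if (schedule$decline_rate == 0) {
      f[post] <- pF
    } else {
      f[post] <- pF * pmax(0, 1 - schedule$decline_rate *
                                (year[post] - yr$release_start))
    }
  }
  f
}

#' @export
print.fishing_schedule <- function(x, ...) {
  lab <- if (x$decline_rate == 0) "control (constant F)" else
    sprintf("release at %.3g%%/yr (F = 0 from %d)", 100 * x$decline_rate,
            x$years$release_start + ceiling(1 / x$decline_rate))
  cat(sprintf("<fishing_schedule> plateau F = %g/yr, %s\n", x$plateau_F, lab))
  invisible(x)
}
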