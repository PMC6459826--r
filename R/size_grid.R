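#' Build a logarithmic body-size grid
#'
#' Discretizes body mass into `n_classes` log-spaced classes spanning
#' `[w_min, w_max]` grams. Class centers form a geometric sequence whose
#' first and last elements are exactly `w_min` and `w_max`; class widths are
#' the mass intervals between the geometric mid-edges, so
#' `widths[i] = centers[i] * (sqrt(r) - 1/sqrt(r))` with
#' `r = (w_max/w_min)^(1/(n_classes - 1))`.
#'
#' @param n_classes Number of size classes (integer, at least 2).
#' @param w_min,w_max Smallest and largest class-center body mass in grams.
#'
#' @return An object of class `size_grid`: a list with elements
#'   `n_classes`, `w_min`, `w_max`, `ratio` (the constant center-to-center
#'   ratio), `centers` and `widths` (numeric vectors of length
#'   `n_classes`, grams).
#'
#' @examples
#' g <- build_size_grid(100, 0.001, 40000)
#' range(g$centers)
#' @export
build_size_grid <- function(n_classes = 100, w_min = 5, w_max = 40000) {
  if (!is_scalar_number(n_classes) || n_classes < 2 || n_classes != round(n_classes)) {
    stop_invalid("`n_classes` must be a single integer >= 2 (got %s)",
                 deparse(n_classes))
  }
  if (!is_scalar_number(w_min) || !is_scalar_number(w_max) ||
      w_min <= 0 || w_max <= 0) {
    stop_invalid("`w_min` and `w_max` must be positive body masses in grams")
  }
  if (w_min >= w_max) {
    stop_invalid("`w_min` (%g) must be strictly smaller than `w_max` (%g)",
                 w_min, w_max)
  }
  n <- as.integer(n_classes)
  ratio <- (w_max / w_min)^(1 / (n - 1))
  centers <- w_min * ratio^(seq_len(n) - 1)
  centers[1] <- w_min
  centers[n] <- w_max
  widths <- centers * (sqrt(ratio) - 1 / sqrt(ratio))
  structure(
    list(n_classes = n, w_min = w_min, w_max = w_max, ratio = ratio,
         centers = centers, widths = widths),
    class = "size_grid"
  )
}

#' @export
print.size_grid <- function(x, ...) {
  cat(sprintf("<size_grid> %d log-spaced classes from %g g to %g g (ratio %.4f)\n",
              x$n_classes, x$w_min, x$w_max, x$ratio))
  invisible(x)
}
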