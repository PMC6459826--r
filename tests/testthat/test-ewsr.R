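test_that("running normalization matches hand-computed z-scores", {
  z <- normalize_running(c(1, 2, 3))
  expect_true(is.na(z[1]))
  expect_equal(z[2], (2 - 1.5) / sd(c(1, 2)), tolerance = 1e-12)
  expect_equal(round(z[2], 4), 0.7071)
  expect_equal(z[3], 1, tolerance = 1e-12)

  zc <- normalize_running(rep(2.5, 8))
  expect_equal(as.numeric(zc[-1]), rep(0, 7))
  expect_true(length(attr(zc, "degenerate")) == 7)
})

test_that("running normalization equals per-year direct evaluation", {
  set.seed(21)
  for (i in 1:50) {
    x <- rnorm(sample(3:60, 1), mean = runif(1, -5, 5), sd = runif(1, 0.1, 9))
    z <- as.numeric(normalize_running(x))
    for (t in 2:length(x)) {
      expect_equal(z[t], (x[t] - mean(x[1:t])) / sd(x[1:t]), tolerance = 1e-10)
    }
  }
})

test_that("missing leading values shift the normalization origin", {
  x <- c(NA, NA, 5, 7, 9)
  z <- as.numeric(normalize_running(x))
  expect_true(all(is.na(z[1:3])))
  expect_equal(z[4], (7 - 6) / sd(c(5, 7)), tolerance = 1e-12)
})

test_that("metric combinations enumerate every non-empty subset", {
  m <- enumerate_metric_combinations()
  expect_length(m, 15)
  expect_true("AR(1) + SD size" %in% names(m))
  expect_true("AR(1) + CV + mean size + SD size" %in% names(m))
  sizes <- vapply(m, length, integer(1))
  expect_true(!is.unsorted(sizes))  # ordered by subset size
  expect_length(enumerate_metric_combinations("CV"), 1)
  expect_length(enumerate_metric_combinations(c("AR1", "CV", "SD_SIZE")), 7)
  expect_error(enumerate_metric_combinations(character(0)), "non-empty")
})

norm_tbl <- function(id, years, values) {
  tibble::tibble(indicator_id = id, year = years, value = values)
}

test_that("composites sum members elementwise and respect missingness", {
  a <- norm_tbl("AR1", 1:2, c(1, 2))
  b <- norm_tbl("SD_SIZE", 1:2, c(0.5, -1))
  comp <- composite_metric(list(a, b))
  expect_equal(comp$value, c(1.5, 1))
  expect_equal(comp$metric_name[1], "AR(1) + SD size")

  single <- composite_metric(list(a))
  expect_equal(single$value, a$value)

  bn <- norm_tbl("SD_SIZE", 1:2, c(NA, -1))
  expect_true(is.na(composite_metric(list(a, bn))$value[1]))

  mismatch <- norm_tbl("CV", 2:3, c(1, 1))
  expect_error(composite_metric(list(a, mismatch)), "year axis")
})

test_that("a recomputed three-indicator composite matches its members", {
  set.seed(5)
  bio <- rlnorm(30, 8, 0.5)
  ser <- tibble::tibble(year = 2010 + seq_along(bio) - 1, biomass = bio,
                        mean_size = rlnorm(30, 4, 0.2),
                        sd_size = rlnorm(30, 3, 0.2))
  ids <- c("AR1", "CV", "SD_SIZE")
  members <- lapply(ids, function(id) {
    normalize_running(compute_indicator_series(ser, id, 2010))
  })
  comp <- composite_metric(members)
  manual <- members[[1]]$value + members[[2]]$value + members[[3]]$value
  expect_equal(comp$value, manual)
  expect_equal(comp$metric_name[1], "AR(1) + CV + SD size")
})

toy_cfg <- detection_config(threshold_sigma = 2, consecutive_k = 2,
                            training = c(2030, 2039),
                            assessment = c(2040, 2090))

test_that("signals fire only above threshold and inside the assessment window", {
  metric <- tibble::tibble(year = 2040:2043, value = c(0, 1, 2.5, 1.9))
  expect_equal(detect_signals(metric, toy_cfg), 2042L)

  # an exceedance in a training year is disregarded
  metric2 <- tibble::tibble(year = c(2035, 2040:2042),
                            value = c(2.5, 0, 0, 0))
  expect_equal(detect_signals(metric2, toy_cfg), integer(0))

  metric3 <- tibble::tibble(year = 2040:2043, value = c(2, 1.99, -3, NA))
  expect_equal(detect_signals(metric3, toy_cfg), integer(0))

  expect_warning(
    out <- detect_signals(tibble::tibble(year = 2000:2005, value = 9),
                          toy_cfg),
    "window")
  expect_equal(out, integer(0))
})

test_that("consecutive filtering keeps only run-completing years", {
  expect_equal(consecutive_filter(c(2041, 2042, 2050), k = 2), 2042L)
  expect_equal(consecutive_filter(c(2041, 2043), k = 2), integer(0))
  ys <- c(2050L, 2041L, 2047L)
  expect_equal(consecutive_filter(ys, k = 1), sort(ys))
  expect_equal(consecutive_filter(2041:2045, k = 3), 2043:2045)
  expect_equal(consecutive_filter(integer(0), k = 2), integer(0))
})

test_that("maximum strength and longest run match brute-force scans", {
  metric <- tibble::tibble(year = 2040:2042, value = c(0.1, 2.2, 1.0))
  expect_equal(max_signal_strength(metric, c(2040, 2042)), 2.2)
  expect_equal(max_signal_strength(metric, c(2042, 2042)), 1.0)
  expect_true(is.na(max_signal_strength(
    tibble::tibble(year = 2040, value = NA_real_), c(2040, 2040))))

  expect_equal(max_consecutive_run(c(2041, 2042, 2043, 2050)), 3L)
  expect_equal(max_consecutive_run(integer(0)), 0L)

  set.seed(31)
  for (i in 1:200) {
    vals <- rnorm(sample(1:40, 1))
    yrs <- sort(sample(2000:2060, length(vals)))
    m <- tibble::tibble(year = yrs, value = vals)
    expect_equal(max_signal_strength(m, c(2000, 2060)), max(vals))
    sig <- sort(sample(2000:2030, sample(0:15, 1)))
    runs <- 0L
    cur <- 0L
    prev <- -Inf
    for (y in sig) {
      cur <- if (y == prev + 1) cur + 1L else 1L
      runs <- max(runs, cur)
      prev <- y
    }
    expect_equal(max_consecutive_run(sig), runs)
  }
})

test_that("detections shrink as the threshold grows and under the consecutive rule", {
  set.seed(17)
  for (i in 1:50) {
    metric <- tibble::tibble(year = 2040:2090, value = rnorm(51, 1, 1.2))
    cfg1 <- detection_config(threshold_sigma = 0.8, training = c(2030, 2039))
    cfg2 <- detection_config(threshold_sigma = 2.0, training = c(2030, 2039))
    s1 <- detect_signals(metric, cfg1)
    s2 <- detect_signals(metric, cfg2)
    expect_true(all(s2 %in% s1))
    expect_true(all(consecutive_filter(s1, 2) %in% s1))
  }
})

test_that("detection configs validate their windows", {
  expect_error(detection_config(threshold_sigma = 0), "> 0")
  expect_error(detection_config(consecutive_k = 0), "positive integer")
  expect_error(detection_config(training = c(2010, 2050)), "before")
  expect_error(detection_config(training = c(2030, 2020)), "ordered")
})
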