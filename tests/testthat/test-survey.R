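write_sizes <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  path
}

test_that("individual size records aggregate to per-year sample moments", {
  path <- write_sizes(data.frame(year = c(2000, 2000, 2001),
                                 size = c(10, 20, 30)))
  out <- read_individual_sizes(path)
  expect_equal(out$mean_size[out$year == 2000], 15)
  expect_equal(out$sd_size[out$year == 2000], sqrt(50), tolerance = 1e-12)
  expect_equal(round(out$sd_size[out$year == 2000], 3), 7.071)
  # a single-record year is flagged with a missing SD
  expect_true(is.na(out$sd_size[out$year == 2001]))
  expect_true(out$flagged[out$year == 2001])

  # duplicate year rows pool before computing moments
  path2 <- write_sizes(data.frame(year = c(2000, 2001, 2000, 2001),
                                  size = c(10, 5, 20, 15)))
  out2 <- read_individual_sizes(path2)
  expect_equal(out2$mean_size, c(15, 10))
  expect_equal(out2$n_records, c(2L, 2L))
})

test_that("malformed survey inputs fail with located errors", {
  path <- write_sizes(data.frame(year = c(2000, 2001), size = c(10, -3)))
  expect_error(read_individual_sizes(path), "row 2")
  empty <- write_sizes(data.frame(year = numeric(0), size = numeric(0)))
  expect_error(read_individual_sizes(empty), "empty")
  nossb <- write_sizes(data.frame(year = 1:3, biomass = 1:3))
  expect_error(read_ssb(nossb), "ssb")
})

test_that("survey fixtures are deterministic and shaped as advertised", {
  d1 <- tempfile(); d2 <- tempfile()
  dir.create(d1); dir.create(d2)
  f1 <- make_survey_fixture("recovering", seed = 18, dir = d1)
  f2 <- make_survey_fixture("recovering", seed = 18, dir = d2)
  expect_identical(readLines(f1$ssb_path), readLines(f2$ssb_path))
  expect_identical(readLines(f1$sizes_path), readLines(f2$sizes_path))

  ssb <- read_ssb(f1$ssb_path)
  n <- nrow(ssb)
  expect_gt(mean(ssb$ssb[(n - 4):n]), mean(ssb$ssb[1:5]))

  f3 <- make_survey_fixture("not_recovering", seed = 18, dir = d1)
  ssb3 <- read_ssb(f3$ssb_path)
  # mean-stationary construction: no strong systematic trend
  expect_lt(abs(cor(ssb3$year, log(ssb3$ssb))), 0.9)
})

test_that("the half-split protocol trains on the first half of the series", {
  fx <- make_survey_fixture("recovering", seed = 18)
  series <- survey_series(read_ssb(fx$ssb_path),
                          read_individual_sizes(fx$sizes_path),
                          stock = "synthetic recovering")
  res <- run_survey_ewsr(series, train_fraction = 0.5)
  expect_length(res$training_years, 15)   # 30-year series -> first 15
  expect_equal(res$training_years, 1989:2003)
  expect_equal(res$assessment_years, 2004:2018)
  expect_equal(nrow(res$report), 15)

  short <- series[1:5, ]
  expect_error(run_survey_ewsr(short), "insufficient")
})

test_that("recovering and stationary fixtures separate at the 2-sigma consecutive rule", {
  rec <- make_survey_fixture("recovering", seed = 18)
  res_rec <- run_survey_ewsr(survey_series(
    read_ssb(rec$ssb_path), read_individual_sizes(rec$sizes_path)))
  expect_gt(res_rec$n_metrics_consecutive, 0)
  hits <- res_rec$report[res_rec$report$n_consecutive_detections > 0, ]
  expect_true(any(hits$includes_size))

  flat <- make_survey_fixture("not_recovering", seed = 18)
  res_flat <- run_survey_ewsr(survey_series(
    read_ssb(flat$ssb_path), read_individual_sizes(flat$sizes_path)))
  expect_equal(res_flat$n_metrics_consecutive, 0)
  expect_equal(sum(res_flat$report$n_consecutive_detections), 0)
})

test_that("survey pipeline reproduces the simulation composites on the same data", {
  ens <- eval_ensemble()
  one <- ens[ens$treatment == "decline_0.1" & ens$replicate == 1, ]
  ser <- tibble::tibble(year = one$year, ssb = one$biomass,
                        mean_size = one$mean_size, sd_size = one$sd_size)
  attr(ser, "analysis_start_year") <- 2010
  res <- run_survey_ewsr(ser, train_fraction = 0.5,
                         analysis_start_year = 2010)

  metrics <- enumerate_metric_combinations()
  direct <- recoverews:::replicate_composites(
    tibble::tibble(year = one$year, biomass = one$biomass,
                   mean_size = one$mean_size, sd_size = one$sd_size),
    2010, metrics)
  for (m in names(metrics)) {
    got <- res$composites$value[res$composites$metric_name == m]
    expect_equal(got, direct$composites[[m]], tolerance = 1e-12)
  }
})

test_that("reading back a written survey series is lossless", {
  fx <- make_survey_fixture("recovering", seed = 9)
  s1 <- survey_series(read_ssb(fx$ssb_path),
                      read_individual_sizes(fx$sizes_path))
  p1 <- tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(s1), p1, row.names = FALSE)
  s2 <- tibble::as_tibble(utils::read.csv(p1))
  expect_equal(s2$year, s1$year)
  expect_equal(s2$ssb, s1$ssb, tolerance = 1e-12)
  expect_equal(s2$mean_size, s1$mean_size, tolerance = 1e-12)
  expect_equal(s2$sd_size, s1$sd_size, tolerance = 1e-12)
})
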