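fake_analysis <- function(results) {
  structure(list(results = results, metric_names = unique(results$metric_name),
                 cfg = detection_config()),
            class = "ews_analysis")
}

toy_results <- function() {
  tibble::tibble(
    treatment = c("decline_0.02", "decline_0.02", "decline_0.02", "control"),
    decline_rate = c(0.02, 0.02, 0.02, 0),
    replicate = c(1L, 2L, 3L, 1L),
    metric_name = "AR(1) + SD size",
    recovery_year = c(2090L, 2070L, 2065L, NA),
    recovered = c(TRUE, TRUE, TRUE, FALSE),
    assess_start = 2040L, assess_end = c(2090L, 2070L, 2065L, 2090L),
    n_signals_single = c(3L, 1L, 0L, 0L),
    first_signal_single = c(2044L, 2055L, NA, NA),
    any_single = c(TRUE, TRUE, FALSE, FALSE),
    first_detection_consecutive = c(2045L, NA, NA, NA),
    any_consecutive = c(TRUE, FALSE, FALSE, FALSE),
    max_strength = c(3.2, 2.4, 1.1, 0.8),
    max_run = c(3L, 1L, 0L, 0L)
  )
}

test_that("replicates classify into TP/FN/FP/TN from windowed detections", {
  res <- toy_results()
  expect_equal(classify_replicate(res, "single"), c("TP", "TP", "FN", "TN"))
  expect_equal(classify_replicate(res, "consecutive"),
               c("TP", "FN", "FN", "TN"))
  fp <- res[4, ]
  fp$any_single <- TRUE
  expect_equal(classify_replicate(fp, "single"), "FP")
})

test_that("ensemble summaries match hand counts, including lead times", {
  s <- summarize_ensemble(fake_analysis(toy_results()), "single")
  rec <- s[s$decline_rate > 0, ]
  expect_equal(rec$n, 3L)
  expect_equal(rec$prop_detected, 2 / 3)
  expect_equal(rec$mean_max_strength, mean(c(3.2, 2.4, 1.1)))
  expect_equal(rec$se_max_strength, sd(c(3.2, 2.4, 1.1)) / sqrt(3))
  # lead time of the first detection: 2090 - 2044 = 46 years
  expect_equal(sort(rec$lead_times[[1]]), c(15, 46))
  expect_true(46 %in% rec$lead_times[[1]])
  ctl <- s[s$decline_rate == 0, ]
  expect_equal(ctl$prop_detected, 0)

  # all-undetected: zero proportion, empty lead-time set
  none <- toy_results()
  none$any_single <- FALSE
  s0 <- summarize_ensemble(fake_analysis(none), "single")
  expect_equal(s0$prop_detected, c(0, 0))
  expect_length(s0$lead_times[[which(s0$decline_rate > 0)]], 0)
})

test_that("full-pipeline analysis produces consistent windows and metrics", {
  an <- ews_analysis(eval_ensemble())
  expect_length(an$metric_names, 15)
  expect_equal(nrow(an$replicates), 6)
  res <- an$results
  expect_equal(nrow(res), 6 * 15)

  rec <- an$replicates[an$replicates$decline_rate > 0, ]
  expect_true(all(rec$recovered))
  expect_true(all(rec$recovery_year > 2040))
  expect_true(all(rec$assess_start == 2040 &
                    rec$assess_end == rec$recovery_year))
  ctl <- an$replicates[an$replicates$decline_rate == 0, ]
  expect_true(all(ctl$assess_start == 2040 & ctl$assess_end == 2090))
  expect_true(all(is.na(ctl$recovery_year)))

  # consecutive detections are never more frequent than single signals
  expect_true(all(res$any_consecutive <= res$any_single))
  expect_true(all(res$max_run <= res$n_signals_single))

  # signals lie inside each replicate's assessment window
  ok <- is.na(res$first_signal_single) |
    (res$first_signal_single >= res$assess_start &
       res$first_signal_single <= res$assess_end)
  expect_true(all(ok))
})

test_that("ROC curves are monotone, bracketed, and match reclassification", {
  an <- ews_analysis(eval_ensemble())
  for (rule in c("single", "consecutive")) {
    roc <- roc_curve(an, "AR(1) + SD size", rule)
    expect_true(2 %in% roc$threshold)
    expect_true(all(diff(roc$tpr) <= 1e-12))
    expect_true(all(diff(roc$fpr) <= 1e-12))
    expect_true(all(roc$tpr >= 0 & roc$tpr <= 1))
    expect_true(all(roc$fpr >= 0 & roc$fpr <= 1))

    # brute-force reclassification at a few thresholds
    roc <- roc_curve(an, "AR(1) + SD size", rule, thresholds = c(0.5, 2, 4))
    comp <- an$composites[an$composites$metric_name == "AR(1) + SD size", ]
    wins <- an$replicates
    for (th in c(0.5, 2, 4)) {
      det <- logical(nrow(wins))
      for (i in seq_len(nrow(wins))) {
        cc <- comp[comp$treatment == wins$treatment[i] &
                     comp$replicate == wins$replicate[i], ]
        cfg_th <- detection_config(threshold_sigma = th)
        sig <- suppressWarnings(detect_signals(
          cc[, c("year", "value")], cfg_th,
          window = c(wins$assess_start[i], wins$assess_end[i])))
        det[i] <- if (rule == "single") length(sig) > 0 else
          length(consecutive_filter(sig, 2)) > 0
      }
      pos <- wins$decline_rate > 0 & wins$recovered
      neg <- wins$decline_rate == 0
      row <- roc[abs(roc$threshold - th) < 1e-9, ]
      expect_equal(row$tpr, mean(det[pos]))
      expect_equal(row$fpr, mean(det[neg]))
    }
  }
  expect_error(roc_curve(ews_analysis(
    eval_ensemble()[eval_ensemble()$decline_rate > 0, ]), "AR(1) + SD size"),
    "control")
})

test_that("the threshold-above-everything and below-everything ROC limits hold", {
  an <- ews_analysis(eval_ensemble())
  roc <- roc_curve(an, "AR(1) + SD size", "single",
                   thresholds = c(1e-6, 1e6))
  expect_equal(roc$tpr[roc$threshold == 1e6], 0)
  expect_equal(roc$fpr[roc$threshold == 1e6], 0)
  expect_equal(roc$tpr[roc$threshold == 1e-6], 1)
})

test_that("training-length sweep covers 2..30 and reproduces the default at 30", {
  ens <- eval_ensemble()
  sweep <- training_length_sweep(ens, "AR(1) + SD size", lengths = 2:30)
  expect_equal(nrow(sweep), 29 * 2)
  expect_setequal(unique(sweep$length), 2:30)
  expect_true(all(c(2, 30) %in% sweep$length))

  an <- ews_analysis(ens)
  res <- an$results[an$results$metric_name == "AR(1) + SD size", ]
  pos <- res[res$decline_rate > 0 & res$recovered, ]
  neg <- res[res$decline_rate == 0, ]
  row <- sweep[sweep$length == 30 & sweep$rule == "single", ]
  expect_equal(row$tp_prop, mean(pos$any_single))
  expect_equal(row$fp_prop, mean(neg$any_single))
  rowc <- sweep[sweep$length == 30 & sweep$rule == "consecutive", ]
  expect_equal(rowc$tp_prop, mean(pos$any_consecutive))
  expect_equal(rowc$fp_prop, mean(neg$any_consecutive))

  expect_error(training_length_sweep(ens, "AR(1) + SD size", lengths = 1:5),
               "below 2")
  expect_error(training_length_sweep(ens, "no such metric"), "unknown metric")
})
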