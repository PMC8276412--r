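test_that("Clopper-Pearson intervals match the exact binomial oracle", {
  # oracle: stats::binom.test implements the same exact construction
  for (n in c(1, 8, 14, 22, 25)) {
    for (x in unique(c(0, 1, n %/% 2, n))) {
      ci <- clopper_pearson(x, n)
      ref <- stats::binom.test(x, n)$conf.int
      expect_equal(c(ci$lower, ci$upper), as.numeric(ref),
                   tolerance = 1e-10)
    }
  }

  # closed forms at the degenerate corners
  for (n in c(1, 8, 10, 20)) {
    expect_equal(clopper_pearson(n, n)$lower, 0.025^(1 / n),
                 tolerance = 1e-10)
    expect_equal(clopper_pearson(0, n)$upper, 1 - 0.025^(1 / n),
                 tolerance = 1e-10)
  }

  # x = 0, n = 10: upper bound solves the binomial tail equation
  up <- uniroot(function(p) pbinom(0, 10, p) - 0.025, c(1e-6, 1 - 1e-6),
                tol = 1e-12)$root
  expect_equal(clopper_pearson(0, 10)$upper, up, tolerance = 1e-8)
  expect_equal(clopper_pearson(0, 10)$upper, 0.3085, tolerance = 1e-4)

  # n = 0 flagged undefined with (0, 1) bounds
  und <- clopper_pearson(0, 0)
  expect_true(und$undefined)
  expect_equal(c(und$lower, und$upper), c(0, 1))
})

test_that("contingency tables build and pool correctly from records", {
  counts <- ala_study_counts()
  low <- counts[counts$dose_group == "low", ]
  t_in <- contingency_table(low$TP[1], low$FP[1], low$FN[1], low$TN[1],
                            "inside", "low")
  t_out <- contingency_table(low$TP[2], low$FP[2], low$FN[2], low$TN[2],
                             "outside", "low")
  pooled <- pool_tables(t_in, t_out, stratum = "overall", dose_group = "low")
  expect_identical(c(pooled$TP, pooled$FP, pooled$FN, pooled$TN),
                   c(13L, 4L, 7L, 22L))

  expect_identical(
    unlist(build_contingency(data.frame(red_positive = logical(0),
                                        histology = character(0)))[1:4]),
    c(TP = 0L, FP = 0L, FN = 0L, TN = 0L))

  rec <- data.frame(red_positive = c(TRUE, TRUE, FALSE, FALSE),
                    histology = c("pos", "neg", "pos", "neg"))
  t1 <- build_contingency(rec)
  expect_identical(c(t1$TP, t1$FP, t1$FN, t1$TN), c(1L, 1L, 1L, 1L))

  rec$red_positive[2] <- NA
  expect_error(build_contingency(rec), "validation error")
})

test_that("predictive values and sensitivity/specificity match the trial", {
  t_lo <- contingency_table(5, 4, 1, 21, "outside", "low")
  pv <- predictive_values(t_lo)
  expect_equal(round_half_away(100 * pv$ppv$estimate), 55.6)
  expect_equal(round_half_away(100 * c(pv$ppv$lower, pv$ppv$upper)),
               c(21.2, 86.3))
  expect_equal(round_half_away(100 * pv$npv$estimate), 95.5)
  expect_equal(round_half_away(100 * c(pv$npv$lower, pv$npv$upper)),
               c(77.2, 99.9))
  ss <- sensitivity_specificity(t_lo)
  expect_equal(round_half_away(100 * ss$sensitivity$estimate), 83.3)
  expect_equal(round_half_away(100 * ss$specificity$estimate), 84.0)

  t_hi_in <- contingency_table(10, 0, 5, 0, "inside", "high")
  ss <- sensitivity_specificity(t_hi_in)
  expect_equal(round_half_away(100 * ss$sensitivity$estimate), 66.7)
  expect_equal(round_half_away(100 * c(ss$sensitivity$lower,
                                       ss$sensitivity$upper)),
               c(38.4, 88.2))

  # zero denominator is flagged, not silently 0/0
  pv0 <- predictive_values(contingency_table(0, 0, 3, 4))
  expect_true(pv0$ppv$undefined)
})

test_that("diagnostic odds ratio and its log-scale interval reproduce the trial", {
  d <- diagnostic_odds_ratio(contingency_table(5, 4, 1, 21))
  expect_equal(round_half_away(d$dor), 26.3)
  expect_equal(d$ci, c(2.38, 288.94), tolerance = 0.01)

  d <- diagnostic_odds_ratio(contingency_table(5, 5, 2, 20))
  expect_equal(d$dor, 10)
  expect_equal(d$ci, c(1.5, 67.6), tolerance = 0.01)

  d <- diagnostic_odds_ratio(contingency_table(15, 5, 7, 20))
  expect_equal(round_half_away(d$dor), 8.6)
  expect_equal(round_half_away(d$ci), c(2.3, 32.4), tolerance = 1e-8)

  # zero cell -> not applicable unless the Haldane correction is requested
  z <- diagnostic_odds_ratio(contingency_table(8, 0, 6, 1))
  expect_false(z$applicable)
  zh <- diagnostic_odds_ratio(contingency_table(8, 0, 6, 1), haldane = TRUE)
  expect_true(zh$applicable)
  expect_equal(zh$dor, (8.5 * 1.5) / (0.5 * 6.5))

  # identity DOR = sens*spec / ((1-sens)(1-spec)) whenever all cells > 0
  set.seed(5)
  for (i in 1:30) {
    cells <- sample(1:40, 4, replace = TRUE)
    t <- contingency_table(cells[1], cells[2], cells[3], cells[4])
    ss <- sensitivity_specificity(t)
    se <- ss$sensitivity$estimate; sp <- ss$specificity$estimate
    expect_equal(diagnostic_odds_ratio(t)$dor,
                 (se * sp) / ((1 - se) * (1 - sp)), tolerance = 1e-12)
  }
})

test_that("proliferative reclassification reproduces the abnormal-tissue PPVs", {
  t_lo <- contingency_table(5, 4, 1, 21, "outside", "low")
  r <- reclassify_abnormal(t_lo, 3)
  expect_equal(round_half_away(100 * predictive_values(r)$ppv$estimate),
               88.9)
  t_hi <- contingency_table(5, 5, 2, 20, "outside", "high")
  r <- reclassify_abnormal(t_hi, 2)
  expect_equal(100 * predictive_values(r)$ppv$estimate, 70)
  expect_identical(unclass(reclassify_abnormal(t_lo, 0)), unclass(t_lo))
  expect_error(reclassify_abnormal(t_lo, 5), "validation error")
})

test_that("study summary applies the trial's suppression rules", {
  rec <- counts_to_records(ala_study_counts())
  rec_ctrl <- data.frame(dose_group = "control", stratum = "outside",
                         red_positive = FALSE, histology = "neg")
  ss <- summarize_study(rbind(rec, rec_ctrl[rep(1, 5), ]))
  expect_setequal(names(ss$summaries),
                  c("low_inside", "low_outside", "low_overall",
                    "high_inside", "high_outside", "high_overall"))
  expect_match(ss$log, "control group excluded", all = FALSE)

  # NPV never reported inside; DOR N/A inside (zero cells); specificity
  # N/A only where no cancer-negative biopsy exists (high dose inside)
  for (d in c("low", "high")) {
    s <- ss$summaries[[paste0(d, "_inside")]]
    expect_null(s$npv)
    expect_false(s$dor$applicable)
  }
  expect_true("specificity" %in% names(ss$summaries$high_inside$suppressed))
  expect_false("specificity" %in% names(ss$summaries$low_inside$suppressed))
  expect_equal(ss$summaries$low_inside$specificity$estimate, 1)
  expect_equal(ss$summaries$low_inside$specificity$lower, 0.025)

  # single-stratum input yields that stratum plus its overall only
  one <- rec[rec$dose_group == "low" & rec$stratum == "outside", ]
  ss1 <- summarize_study(one)
  expect_setequal(names(ss1$summaries), c("low_outside", "low_overall"))
})

test_that("half-away rounding matches the printed convention", {
  expect_equal(round_half_away(26.25), 26.3)  # round() would give 26.2
  expect_equal(round_half_away(-26.25), -26.3)
  expect_equal(round_half_away(0.625, 2), 0.63)
})
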