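test_that("imprecision computes intraday and pooled interday CVs", {
  # degenerate: identical values in every run
  flat <- imprecision(rep(5, 18), rep(c("R1", "R2", "R3"), each = 6))
  expect_equal(unname(flat$intraday_cv_pct), c(0, 0, 0))
  expect_equal(flat$interday_cv_pct, 0)
  expect_true(flat$pass)

  # one run {9, 10, 11}: sd 1, mean 10
  one <- imprecision(c(9, 10, 11), rep("R1", 3))
  expect_equal(unname(one$intraday_cv_pct), 10)
  expect_true(is.na(one$interday_cv_pct))

  expect_error(imprecision(c(-1, 1), c("R1", "R1")), "zero")
  expect_error(imprecision(c(1, 2, 3), c("R1", "R2", "R3")), "2 replicates")

  # threshold edge: a CV beyond 15% fails
  bad <- imprecision(rep(c(84, 116), 3), rep(c("R1", "R2", "R3"), each = 2))
  expect_gt(max(bad$intraday_cv_pct), 15)
  expect_false(bad$pass)
})

test_that("pooled interday CV recovers injected variance components", {
  # Monte-Carlo parameter recovery, 3 runs x 6 replicates, intraday 5%,
  # between-run 7%: the pooled estimator's own sampling distribution
  # (bounds frozen from a brute-force oracle) has mean ~7.4%
  set.seed(404)
  est <- replicate(300, {
    vals <- unlist(lapply(1:3, function(r) {
      100 * exp(stats::rnorm(1, 0, 0.07)) * (1 + stats::rnorm(6, 0, 0.05))
    }))
    imprecision(vals, rep(c("R1", "R2", "R3"), each = 6))$interday_cv_pct
  })
  expect_gt(mean(est), 6.9)
  expect_lt(mean(est), 7.9)
})

test_that("accuracy compares measured means against the nominal level", {
  expect_equal(accuracy(c(10, 10, 10), 10)$accuracy_pct, 100)
  expect_true(accuracy(c(10, 10, 10), 10)$pass)
  # published-magnitude cases: 87% passes at +/-15, 119% fails
  expect_equal(accuracy(c(8.5, 8.7, 8.9), 10)$accuracy_pct, 87)
  expect_true(accuracy(c(8.5, 8.7, 8.9), 10)$pass)
  a <- accuracy(c(11.8, 11.9, 12.0), 10)
  expect_equal(a$accuracy_pct, 119)
  expect_false(a$pass)
  expect_error(accuracy(c(1, 2), 0), "> 0")
})

test_that("LOQ estimation applies the CV/SNR rule with monotone closure", {
  lv <- tibble::tibble(conc = c(0.01, 0.02, 0.05, 0.1, 0.5),
                       cv_pct = c(35, 12, 8, 5, 3),
                       mean_snr = c(12, 15, 30, 60, 300))
  expect_equal(estimate_loq(lv)$loq, 0.02)

  all_pass <- lv
  all_pass$cv_pct <- rep(5, 5)
  expect_equal(estimate_loq(all_pass)$loq, 0.01)

  # a noisy mid-level blocks every level below it
  gap <- all_pass
  gap$cv_pct[3] <- 50
  expect_equal(estimate_loq(gap)$loq, 0.1)

  none <- lv
  none$mean_snr <- rep(2, 5)
  expect_false(estimate_loq(none)$reached)
  expect_true(is.na(estimate_loq(none)$loq))

  unsorted <- lv[c(2, 1, 3, 4, 5), ]
  expect_error(estimate_loq(unsorted), "ascending")

  # monotonicity: raising every SNR never raises the LOQ
  better <- lv
  better$mean_snr <- lv$mean_snr * 10
  expect_lte(estimate_loq(better)$loq, estimate_loq(lv)$loq)
})

test_that("recovery and matrix effect are area-mean ratios in percent", {
  expect_equal(recovery(c(1, 2, 3), c(1, 2, 3)), 100)
  expect_equal(recovery(c(300, 310, 320), c(990, 1000, 1010)), 31)
  expect_equal(recovery(c(830, 840, 850), c(990, 1000, 1010)), 84)
  expect_error(recovery(numeric(0), 1), "non-empty")

  expect_equal(matrix_effect(c(5, 5), c(5, 5)), 100)
  expect_equal(matrix_effect(c(840, 850, 860), c(990, 1000, 1010)), 85)
  expect_equal(matrix_effect(c(0, 0), c(10, 10)), 0)
  expect_error(matrix_effect(c(1, 2), numeric(0)), "non-empty")
})

test_that("carryover applies the 0.01% bound", {
  expect_equal(carryover(0, 10000)$carryover_pct, 0)
  ok <- carryover(0.5, 10000)
  expect_equal(ok$carryover_pct, 0.005)
  expect_true(ok$pass)
  bad <- carryover(2, 10000)
  expect_equal(bad$carryover_pct, 0.02)
  expect_false(bad$pass)
  expect_error(carryover(1, 0), "> 0")
})

test_that("hct robustness normalizes to the reference hematocrit", {
  # flat series: all deviations zero, the whole grid passes
  flat <- hct_robustness(seq(0.3, 0.7, 0.1), rep(2, 5))
  expect_true(all(flat$table$deviation_pct == 0))
  expect_equal(unname(flat$pass_range), c(0.3, 0.7))

  # concentrations generated by the compartment model itself reproduce the
  # analytic bias profile, so the pass range covers 0.30-0.50 for a 4:1 analyte
  hs <- seq(0.30, 0.70, 0.05)
  conc <- vapply(hs, function(h) {
    as.numeric(serum_from_vams(vams_from_serum(2, t_spec, h), t_spec, 0.4))
  }, numeric(1))
  hr <- hct_robustness(hs, conc)
  expect_lte(hr$pass_range["low"], 0.30)
  expect_gte(hr$pass_range["high"], 0.50)
  prof <- hct_bias_profile(t_spec, hs)
  expect_equal(hr$table$deviation_pct, prof$deviation_pct, tolerance = 1e-9)

  # degenerate single point at the reference
  single <- hct_robustness(0.4, 2)
  expect_equal(unname(single$pass_range), c(0.4, 0.4))
  # interpolable reference
  interp <- hct_robustness(c(0.35, 0.45), c(2, 2))
  expect_equal(interp$table$deviation_pct[interp$table$hct == 0.4], 0)
  expect_error(hct_robustness(c(0.5, 0.6), c(2, 2)), "interpolable")
})

test_that("stability classification walks the scheduled days", {
  days <- c(0, 1, 3, 5, 7, 14, 28)
  flat <- stability_assess(rep(days, each = 2), rep(10, 14), temp_c = -18)
  expect_equal(flat$stable_days, Inf)
  expect_equal(flat$label, ">28")
  expect_true(flat$pass_28d)

  # 14% down at day 14 still passes; 18% down at day 28 stops the walk
  conc <- 10 * c(1, 1, 1, 1, 1, 0.86, 0.82)
  s <- stability_assess(days, conc, temp_c = 20)
  expect_equal(s$stable_days, 14)
  expect_equal(s$label, "14")
  expect_false(s$pass_28d)

  # 20% down on day 1: nothing beyond day 0 is stable
  s0 <- stability_assess(days, 10 * c(1, 0.8, 0.8, 0.8, 0.8, 0.8, 0.8))
  expect_equal(s0$stable_days, 0)

  expect_error(stability_assess(c(1, 3), c(1, 1)), "day 0")

  # monotone in the tolerance
  loose <- stability_assess(days, conc, thresholds = threshold_config(stability_tol_pct = 25))
  expect_gte(loose$stable_days, s$stable_days)
})

test_that("scale invariance holds for every ratio-based statistic", {
  set.seed(505)
  x <- 100 * (1 + stats::rnorm(18, 0, 0.05))
  runs <- rep(c("R1", "R2", "R3"), each = 6)
  k <- 12.34
  p1 <- imprecision(x, runs)
  p2 <- imprecision(k * x, runs)
  expect_equal(p2$intraday_cv_pct, p1$intraday_cv_pct)
  expect_equal(p2$interday_cv_pct, p1$interday_cv_pct)
  expect_equal(recovery(k * c(8, 9), k * c(10, 11)), recovery(c(8, 9), c(10, 11)))
  expect_equal(matrix_effect(k * c(8, 9), k * c(10, 11)),
               matrix_effect(c(8, 9), c(10, 11)))
  expect_equal(carryover(k * 0.5, k * 1e4)$carryover_pct,
               carryover(0.5, 1e4)$carryover_pct)
  expect_equal(accuracy(k * c(9, 10), k * 10)$accuracy_pct,
               accuracy(c(9, 10), 10)$accuracy_pct)
})

test_that("validation reports gate on the FDA components", {
  prec_ok <- imprecision(rep(c(99, 100, 101), 3), rep(c("R1", "R2", "R3"), 3))
  acc_ok <- accuracy(c(10, 10.2), 10)
  cal_ok <- fit_calibration(c(1, 2, 5, 10, 20, 50), 0.02 * c(1, 2, 5, 10, 20, 50))
  loq_ok <- list(loq = 0.02, reached = TRUE)
  co_ok <- carryover(0.1, 1e4)
  stab_ok <- stability_assess(c(0, 28), c(10, 9.9), temp_c = -18)

  rep_ok <- validation_report("T", precision = prec_ok, accuracy_result = acc_ok,
                              calibration = cal_ok, loq = loq_ok,
                              carryover_result = co_ok, stability = list(stab_ok),
                              recovery_pct = 84, matrix_effect_pct = 92)
  expect_true(rep_ok$overall_pass)

  # a single failing component (CV 16% vs limit 15%) flips the overall verdict
  prec_bad <- imprecision(rep(c(84, 116), 3), rep(c("R1", "R2", "R3"), each = 2))
  rep_bad <- validation_report("T", precision = prec_bad, accuracy_result = acc_ok,
                               calibration = cal_ok, loq = loq_ok,
                               carryover_result = co_ok, stability = list(stab_ok))
  expect_false(rep_bad$overall_pass)
  expect_false(rep_bad$component_pass$precision)

  # missing components are reported as not assessed, with a warning
  expect_warning(
    rep_na <- validation_report("T", precision = prec_ok, accuracy_result = acc_ok),
    "not assessed")
  expect_true("carryover" %in% rep_na$not_assessed)
  expect_true(rep_na$overall_pass)
})
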