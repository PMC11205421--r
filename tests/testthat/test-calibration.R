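test_that("area ratios divide analyte by internal-standard area", {
  expect_equal(area_ratio(500, 1000), 0.5)
  expect_equal(area_ratio(0, 1000), 0)
  expect_error(area_ratio(7, 0), "istd_area must be > 0")
  expect_error(area_ratio(c(1, 7), c(10, 0), sample_id = c("a", "b")), "b")
})

test_that("noiseless calibrators are fitted exactly, for both weightings", {
  conc <- c(1, 2, 5, 10, 20, 50)
  for (w in c("none", "1/x")) {
    cc <- fit_calibration(conc, 0.02 * conc, weighting = w)
    expect_equal(cc$slope, 0.02)
    expect_equal(cc$intercept, 0)
    expect_equal(cc$r2, 1)
    expect_true(cc$linear_ok)
  }
})

test_that("blank correction makes the fit invariant to a constant response shift", {
  conc <- c(1, 2, 5, 10, 20, 50)
  ratio <- 0.02 * conc + 0.003
  base <- fit_calibration(conc, ratio, blank_ratio = 0.003)
  shifted <- fit_calibration(conc, ratio + 0.1, blank_ratio = 0.103)
  expect_equal(shifted$slope, base$slope)
  expect_equal(shifted$intercept, base$intercept)
  expect_equal(shifted$r2, base$r2)
})

test_that("replicate calibrator ratios are averaged per level before fitting", {
  conc <- rep(c(1, 5, 10), each = 2)
  ratio <- c(0.9, 1.1, 4.9, 5.1, 9.9, 10.1) * 0.01
  cc <- fit_calibration(conc, ratio)
  expect_equal(cc$n_levels, 3)
  expect_equal(cc$slope, 0.01, tolerance = 1e-10)
})

test_that("degenerate calibrator sets are rejected", {
  expect_error(fit_calibration(c(1, 2), c(0.1, 0.2)), "3 distinct")
  expect_error(fit_calibration(c(5, 5, 5), c(0.1, 0.2, 0.3)), "3 distinct")
  expect_error(fit_calibration(c(0, 1, 2), c(0, 0.1, 0.2)), "must be > 0")
  expect_error(fit_calibration(c(1, 2, 5), c(0.1, 0.2, 0.5), blank_ratio = -1),
               "blank_ratio")
})

test_that("OLS recovers a known slope within its own sampling error", {
  # synthetic lines at slope 0.05, intercept 0.01, tiny gaussian ratio noise:
  # the fitted slope should land within 3 standard errors essentially always
  set.seed(202)
  conc <- c(1, 2, 5, 10, 20, 50)
  hits <- 0
  n_rep <- 200
  for (i in seq_len(n_rep)) {
    y <- 0.01 + 0.05 * conc + stats::rnorm(6, 0, 1e-4)
    fit <- stats::lm(y ~ conc)
    se <- summary(fit)$coefficients["conc", "Std. Error"]
    cc <- fit_calibration(conc, y)
    expect_equal(cc$slope, unname(stats::coef(fit)[2]))
    if (abs(cc$slope - 0.05) <= 3 * se) hits <- hits + 1
  }
  # the slope t-statistic has 4 df here, so +/-3 SE covers P(|t4|<=3) ~ 0.96
  expect_gte(hits / n_rep, 0.92)
})

test_that("quantification inverts the response construction", {
  conc <- c(1, 2, 5, 10, 20, 50)
  cc <- fit_calibration(conc, 0.02 * conc, analyte = "F")
  # every calibrator level is returned exactly
  q <- quantify(0.02 * conc, cc, panel[["F"]])
  expect_equal(q$conc, conc, tolerance = 1e-9)
  # levels under cortisol's 2.5 ng/mL LOQ are recovered but censored
  expect_equal(q$below_loq, conc < panel[["F"]]$loq)
  # a blank-level response quantifies to zero, censored
  q0 <- quantify(cc$blank_ratio + cc$intercept, cc, panel[["F"]])
  expect_equal(q0$conc, 0)
  expect_true(q0$below_loq)
})

test_that("concentrations below the LOQ are reported but censored", {
  conc <- c(0.02, 0.05, 0.2, 1, 4, 16)
  cc <- fit_calibration(conc, 0.1 * conc, analyte = "T")
  q <- quantify(0.1 * 0.01, cc, t_spec)
  expect_equal(q$conc, 0.01, tolerance = 1e-9)
  expect_true(q$below_loq)
  # negative back-calculated values clamp to zero with the truncation flag
  qn <- quantify(-0.005, cc, t_spec)
  expect_equal(qn$conc, 0)
  expect_true(qn$truncated)
})

test_that("rejected curves refuse to quantify", {
  conc <- c(1, 2, 5, 10, 20, 50)
  set.seed(7)
  bad <- fit_calibration(conc, 0.02 * sqrt(conc) + rnorm(6, 0, 0.01),
                         thresholds = threshold_config(r2_min = 0.999))
  expect_false(bad$linear_ok)
  expect_error(quantify(0.1, bad, t_spec), "rejected")
})

test_that("quantification is invariant to blank shifts and common area scaling", {
  set.seed(303)
  conc <- c(1, 2, 5, 10, 20, 50)
  ratio <- 0.02 * conc * (1 + stats::rnorm(6, 0, 0.01))
  sample_ratio <- 0.02 * 7
  for (w in c("none", "1/x")) {
    base <- quantify(sample_ratio,
                     fit_calibration(conc, ratio, 0, weighting = w), t_spec)$conc
    shifted <- quantify(sample_ratio + 0.25,
                        fit_calibration(conc, ratio + 0.25, 0.25, weighting = w),
                        t_spec)$conc
    expect_equal(shifted, base, tolerance = 1e-10)
    # scaling analyte and ISTD areas together leaves ratios, hence results,
    # untouched (the ISTD normalization property)
    k <- 37.5
    scaled_ratio <- area_ratio(k * ratio * 1000, k * 1000)
    expect_equal(scaled_ratio, ratio)
    scaled <- quantify(area_ratio(k * sample_ratio * 1000, k * 1000),
                       fit_calibration(conc, scaled_ratio, 0, weighting = w),
                       t_spec)$conc
    expect_equal(scaled, base, tolerance = 1e-10)
  }
})
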