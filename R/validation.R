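# Method-validation battery: imprecision, accuracy, LOQ, recovery, matrix
# effects, carryover, hematocrit robustness and storage stability, each with
# pass/fail evaluation against a threshold_config.

#' Intraday and interday imprecision
#'
#' Intraday CV is computed per analytical run as `100 * sd / mean` of the
#' run's peak area ratios; interday CV pools all values across runs. (An
#' ANOVA variance-component decomposition is available via
#' `method = "anova"`, which removes the within-run component from the
#' between-run variance estimate.)
#'
#' @param ratio peak area ratios (or concentrations) of the replicate
#'   measurements.
#' @param run_id parallel vector identifying the analytical run of each value.
#' @param thresholds a [threshold_config()].
#' @param method `"pooled"` (default) or `"anova"` for the interday estimate.
#' @return an object of class `vams_precision`: `intraday_cv_pct` (named, one
#'   per run), `interday_cv_pct`, `n_runs`, `n_per_run`, `pass`.
#' @export
#' @examples
#' imprecision(c(9, 10, 11), rep("R1", 3))$intraday_cv_pct   # 10
imprecision <- function(ratio, run_id, thresholds = threshold_config(),
                        method = c("pooled", "anova")) {
  method <- match.arg(method)
  stopifnot(length(ratio) == length(run_id), inherits(thresholds, "threshold_config"))
  groups <- split(ratio, run_id)
  if (any(lengths(groups) < 2L)) {
    stop("each run needs at least 2 replicates", call. = FALSE)
  }
  intraday <- vapply(groups, cv_pct, numeric(1))
  if (length(groups) >= 2L) {
    interday <- if (method == "pooled") {
      cv_pct(ratio)
    } else {
      fit <- stats::aov(ratio ~ factor(run_id))
      ms <- summary(fit)[[1]][["Mean Sq"]]
      n_per <- mean(lengths(groups))
      between_var <- max((ms[1] - ms[2]) / n_per, 0)
      100 * sqrt(between_var + ms[2]) / mean(ratio)
    }
  } else {
    interday <- NA_real_
  }
  structure(
    list(intraday_cv_pct = intraday, interday_cv_pct = interday,
         n_runs = length(groups), n_per_run = lengths(groups),
         pass = max(intraday) <= thresholds$cv_max_pct &&
           (is.na(interday) || interday <= thresholds$cv_max_pct)),
    class = "vams_precision"
  )
}

#' Accuracy against a nominal concentration
#'
#' `100 * mean(measured) / nominal`; acceptable when within
#' `accuracy_tol_pct` of 100%.
#'
#' @param measured back-calculated concentrations, ng/mL.
#' @param nominal the target concentration, ng/mL, > 0.
#' @param thresholds a [threshold_config()].
#' @return list with `accuracy_pct` and `pass`.
#' @export
accuracy <- function(measured, nominal, thresholds = threshold_config()) {
  if (!is_scalar_number(nominal) || nominal <= 0) {
    stop("nominal must be > 0", call. = FALSE)
  }
  if (length(measured) < 1L) stop("at least one measurement is required", call. = FALSE)
  value <- 100 * mean(measured) / nominal
  list(accuracy_pct = value,
       pass = abs(100 - value) <= thresholds$accuracy_tol_pct)
}

#' Summarize replicate measurements per LOQ level
#'
#' Convenience builder for [estimate_loq()]: computes the CV of the
#' back-calculated concentrations and the mean SNR per concentration level.
#'
#' @param conc nominal level of each replicate, ng/mL.
#' @param measured back-calculated concentration of each replicate.
#' @param snr signal-to-noise ratio of each replicate.
#' @return a tibble with columns `conc`, `cv_pct`, `mean_snr`, sorted by
#'   `conc`.
#' @export
loq_level_summary <- function(conc, measured, snr) {
  stopifnot(length(conc) == length(measured), length(conc) == length(snr))
  levels <- sort(unique(conc))
  cv <- vapply(levels, function(l) cv_pct(measured[conc == l]), numeric(1))
  msnr <- vapply(levels, function(l) mean(snr[conc == l]), numeric(1))
  tibble::tibble(conc = levels, cv_pct = cv, mean_snr = msnr)
}

#' Estimate the limit of quantification
#'
#' The LOQ is the lowest tested level at which the replicate CV stays within
#' `loq_cv_max_pct`, the mean signal-to-noise ratio reaches `loq_min_snr`,
#' and every higher level also passes (monotone closure — a noisy mid-level
#' cannot certify a lower LOQ).
#'
#' @param levels a data frame with columns `conc` (strictly ascending,
#'   distinct), `cv_pct`, `mean_snr`; see [loq_level_summary()].
#' @param thresholds a [threshold_config()].
#' @return list with `loq` (ng/mL, or `NA` when no level qualifies) and
#'   `reached` (logical).
#' @export
estimate_loq <- function(levels, thresholds = threshold_config()) {
  stopifnot(is.data.frame(levels),
            all(c("conc", "cv_pct", "mean_snr") %in% names(levels)))
  conc <- levels$conc
  if (any(diff(conc) <= 0)) {
    stop("levels must be sorted strictly ascending with no duplicates", call. = FALSE)
  }
  if (nrow(levels) < 2L) stop("at least 2 levels are required", call. = FALSE)
  pass <- levels$cv_pct <= thresholds$loq_cv_max_pct &
    levels$mean_snr >= thresholds$loq_min_snr
  suffix_ok <- rev(cumprod(rev(pass))) == 1
  if (!any(suffix_ok)) return(list(loq = NA_real_, reached = FALSE))
  list(loq = conc[which(suffix_ok)[1]], reached = TRUE)
}

#' Extraction recovery
#'
#' Ratio of mean peak areas of samples spiked before extraction to samples
#' spiked after extraction (immediately before injection), in percent.
#'
#' @param pre_spiked_areas areas of the pre-extraction-spiked set.
#' @param post_spiked_areas areas of the post-extraction-spiked set.
#' @return recovery in percent.
#' @export
recovery <- function(pre_spiked_areas, post_spiked_areas) {
  if (length(pre_spiked_areas) == 0 || length(post_spiked_areas) == 0) {
    stop("both area sets must be non-empty", call. = FALSE)
  }
  post_mean <- mean(post_spiked_areas)
  if (post_mean <= 0) stop("mean of post-spiked areas must be > 0", call. = FALSE)
  100 * mean(pre_spiked_areas) / post_mean
}

#' Matrix effect
#'
#' Mean peak area of matrix-spiked extracts (A) over solvent-spiked extracts
#' (B), in percent: values below 100 indicate ion suppression, above 100
#' enhancement.
#'
#' @param matrix_spiked_areas areas of the spiked matrix extracts (A).
#' @param solvent_spiked_areas areas of the spiked solvent extracts (B).
#' @return `100 * mean(A) / mean(B)`.
#' @export
matrix_effect <- function(matrix_spiked_areas, solvent_spiked_areas) {
  if (length(matrix_spiked_areas) == 0 || length(solvent_spiked_areas) == 0) {
    stop("both area sets must be non-empty", call. = FALSE)
  }
  b_mean <- mean(solvent_spiked_areas)
  if (b_mean <= 0) stop("mean of solvent-spiked areas must be > 0", call. = FALSE)
  100 * mean(matrix_spiked_areas) / b_mean
}

#' Injection carryover
#'
#' Residual signal in a blank injected immediately after a sample at the
#' upper working range, as a percentage of the high sample's area.
#'
#' @param blank_after_high_area analyte area in the trailing blank.
#' @param high_area analyte area of the preceding high sample, > 0.
#' @param thresholds a [threshold_config()].
#' @return list with `carryover_pct` and `pass`.
#' @export
carryover <- function(blank_after_high_area, high_area,
                      thresholds = threshold_config()) {
  if (!is_scalar_number(high_area) || high_area <= 0) {
    stop("high_area must be > 0", call. = FALSE)
  }
  value <- 100 * blank_after_high_area / high_area
  list(carryover_pct = value, pass = value <= thresholds$carryover_max_pct)
}

#' Hematocrit robustness of measured concentrations
#'
#' Expresses measured concentrations over a hematocrit series as percent
#' deviations from the concentration at the reference (standardization)
#' hematocrit, and finds the maximal contiguous hematocrit range around the
#' reference where all deviations stay within `hct_dev_max_pct`. Replicates
#' at the same hematocrit are averaged; if the reference hematocrit was not
#' itself measured, the reference concentration is linearly interpolated.
#'
#' @param hct hematocrit of each measurement, fractions.
#' @param conc measured concentration of each measurement, ng/mL.
#' @param ref_hct reference hematocrit (default 0.40).
#' @param thresholds a [threshold_config()].
#' @return list with `table` (tibble `hct`, `mean_conc`, `deviation_pct`),
#'   `pass_range` (`(low, high)` fractions) and `pass`.
#' @export
hct_robustness <- function(hct, conc, ref_hct = 0.4,
                           thresholds = threshold_config()) {
  stopifnot(length(hct) == length(conc))
  check_hct(hct)
  levels <- sort(unique(hct))
  means <- vapply(levels, function(h) mean(conc[hct == h]), numeric(1))
  if (!ref_hct %in% levels) {
    if (length(levels) < 2L || ref_hct < min(levels) || ref_hct > max(levels)) {
      stop("reference hematocrit is neither measured nor interpolable", call. = FALSE)
    }
    ref_conc <- stats::approx(levels, means, xout = ref_hct)$y
    ord <- order(c(levels, ref_hct))
    means <- c(means, ref_conc)[ord]
    levels <- c(levels, ref_hct)[ord]
  } else {
    ref_conc <- means[levels == ref_hct]
  }
  if (ref_conc <= 0) stop("reference concentration must be > 0", call. = FALSE)
  deviation <- 100 * (means / ref_conc - 1)
  ok <- abs(deviation) <= thresholds$hct_dev_max_pct
  i_ref <- which(levels == ref_hct)
  lo <- i_ref
  while (lo > 1 && ok[lo - 1]) lo <- lo - 1
  hi <- i_ref
  while (hi < length(levels) && ok[hi + 1]) hi <- hi + 1
  list(table = tibble::tibble(hct = levels, mean_conc = means,
                              deviation_pct = deviation),
       pass_range = c(low = levels[lo], high = levels[hi]),
       pass = TRUE)
}

#' Storage stability of a concentration-time series
#'
#' Replicates at each scheduled storage day are averaged; a day passes when
#' its mean concentration is within `stability_tol_pct` of the day-0 mean.
#' `stable_days` is the largest scheduled day such that every day up to and
#' including it passes; when the final scheduled day (28) passes, the series
#' is reported with the `">28"` sentinel (`stable_days = Inf`).
#'
#' @param days storage day of each measurement.
#' @param conc measured concentration of each measurement, ng/mL.
#' @param temp_c storage temperature, for labelling.
#' @param thresholds a [threshold_config()].
#' @return an object of class `vams_stability`: `temp_c`, `table` (tibble
#'   `days`, `mean_conc`, `deviation_pct`, `pass`), `stable_days` (numeric,
#'   `Inf` = beyond the schedule), `label` (e.g. `"14"` or `">28"`),
#'   `pass_28d`.
#' @export
stability_assess <- function(days, conc, temp_c = NA_real_,
                             thresholds = threshold_config()) {
  stopifnot(length(days) == length(conc))
  sched <- sort(unique(days))
  if (!0 %in% sched) stop("day 0 measurements are missing", call. = FALSE)
  means <- vapply(sched, function(d) mean(conc[days == d]), numeric(1))
  c0 <- means[sched == 0]
  if (c0 <= 0) stop("day 0 mean concentration must be > 0", call. = FALSE)
  deviation <- 100 * (means / c0 - 1)
  pass <- abs(deviation) <= thresholds$stability_tol_pct
  stable_days <- 0
  for (i in seq_along(sched)) {
    if (!pass[i]) break
    stable_days <- sched[i]
  }
  last_day <- max(sched)
  pass_last <- stable_days == last_day
  structure(
    list(temp_c = temp_c,
         table = tibble::tibble(days = sched, mean_conc = means,
                                deviation_pct = deviation, pass = pass),
         stable_days = if (pass_last) Inf else stable_days,
         label = if (pass_last) paste0(">", last_day) else as.character(stable_days),
         pass_28d = pass_last && last_day >= 28),
    class = "vams_stability"
  )
}

#' Assemble a per-analyte validation report
#'
#' Aggregates the component results of the validation battery and evaluates
#' the overall pass. Gated components (precision, accuracy, calibration
#' linearity, LOQ reachability, carryover, frozen-storage stability) enter
#' the conjunction; recovery, matrix effect and the hematocrit pass range are
#' reported for interpretation but do not gate (no numeric acceptance bound
#' exists for them). Missing components are reported as not assessed,
#' excluded from the conjunction, and counted in `n_not_assessed` with a
#' warning.
#'
#' @param analyte analyte code.
#' @param precision a `vams_precision` or `NULL`.
#' @param accuracy_result result of [accuracy()] or `NULL`.
#' @param calibration a `vams_calibration`, a list of them (one per run, all
#'   of which must be accepted for the linearity gate), or `NULL`.
#' @param loq result of [estimate_loq()] or `NULL`.
#' @param recovery_pct scalar from [recovery()] or `NULL`.
#' @param matrix_effect_pct scalar from [matrix_effect()] or `NULL`.
#' @param carryover_result result of [carryover()] or `NULL`.
#' @param hct result of [hct_robustness()] or `NULL`.
#' @param stability list of `vams_stability` (one per storage temperature) or
#'   `NULL`. The frozen (lowest-temperature) series gates `overall_pass` via
#'   its day-28 pass.
#' @param selectivity_pass logical pass-through from chromatographic review
#'   (not computable from peak areas).
#' @param thresholds a [threshold_config()].
#' @return an object of class `vams_validation_report`.
#' @export
validation_report <- function(analyte, precision = NULL, accuracy_result = NULL,
                              calibration = NULL, loq = NULL,
                              recovery_pct = NULL, matrix_effect_pct = NULL,
                              carryover_result = NULL, hct = NULL,
                              stability = NULL, selectivity_pass = NA,
                              thresholds = threshold_config()) {
  gates <- list()
  if (!is.null(precision)) gates$precision <- precision$pass
  if (!is.null(accuracy_result)) gates$accuracy <- accuracy_result$pass
  if (!is.null(calibration)) {
    curves <- if (inherits(calibration, "vams_calibration")) list(calibration)
              else calibration
    gates$linearity <- all(vapply(curves, `[[`, logical(1), "linear_ok"))
  }
  if (!is.null(loq)) gates$loq <- loq$reached
  if (!is.null(carryover_result)) gates$carryover <- carryover_result$pass
  frozen <- NULL
  if (!is.null(stability) && length(stability)) {
    temps <- vapply(stability, `[[`, numeric(1), "temp_c")
    frozen <- stability[[which.min(temps)]]
    gates$stability <- frozen$pass_28d
  }
  all_components <- c("precision", "accuracy", "linearity", "loq", "carryover",
                      "stability")
  missing <- setdiff(all_components, names(gates))
  if (length(missing)) {
    warning("components not assessed for ", analyte, ": ",
            paste(missing, collapse = ", "), call. = FALSE)
  }
  structure(
    list(analyte = analyte, precision = precision, accuracy = accuracy_result,
         calibration = calibration, loq = loq, recovery_pct = recovery_pct,
         matrix_effect_pct = matrix_effect_pct, carryover = carryover_result,
         hct = hct, hct_pass_range = if (!is.null(hct)) hct$pass_range else NULL,
         stability = stability, selectivity_pass = selectivity_pass,
         component_pass = gates, not_assessed = missing,
         n_not_assessed = length(missing),
         overall_pass = all(unlist(gates)),
         thresholds = thresholds),
    class = "vams_validation_report"
  )
}

#' @export
print.vams_validation_report <- function(x, ...) {
  cat(sprintf("<vams_validation_report> %s — overall %s\n", x$analyte,
              if (x$overall_pass) "PASS" else "FAIL"))
  for (nm in names(x$component_pass)) {
    cat(sprintf("  %-10s %s\n", nm, if (x$component_pass[[nm]]) "pass" else "FAIL"))
  }
  if (!is.null(x$recovery_pct)) {
    cat(sprintf("  recovery %.1f%%, matrix effect %.1f%%\n",
                x$recovery_pct, x$matrix_effect_pct %||% NA_real_))
  }
  if (!is.null(x$hct_pass_range)) {
    cat(sprintf("  Hct pass range %.2f-%.2f\n",
                x$hct_pass_range[1], x$hct_pass_range[2]))
  }
  if (length(x$not_assessed)) {
    cat("  not assessed:", paste(x$not_assessed, collapse = ", "), "\n")
  }
  invisible(x)
}
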