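# Internal-standard calibration: area ratios, blank-corrected linear fits,
# and quantification with LOQ censoring.

#' Analyte/internal-standard peak area ratio
#'
#' Quantification never uses raw areas: normalizing by the co-extracted
#' stable-isotope internal standard cancels preparation and detection losses.
#'
#' @param analyte_area analyte peak area(s), >= 0.
#' @param istd_area internal standard peak area(s), > 0.
#' @param sample_id optional identifier(s) used in error messages.
#' @return `analyte_area / istd_area`.
#' @export
area_ratio <- function(analyte_area, istd_area, sample_id = NULL) {
  check_nonneg(analyte_area, "analyte_area")
  bad <- !is.finite(istd_area) | istd_area <= 0
  if (any(bad)) {
    where <- if (!is.null(sample_id)) {
      paste0(" (sample ", paste(sample_id[bad], collapse = ", "), ")")
    } else ""
    stop("istd_area must be > 0", where, call. = FALSE)
  }
  analyte_area / istd_area
}

#' Fit a blank-corrected calibration curve
#'
#' Ordinary least squares of the blank-corrected area ratio on the nominal
#' concentration. The run's blank area ratio (endogenous residue in the
#' surrogate matrix) is subtracted from every calibrator response before
#' fitting, so the curve describes the added analyte only. Replicate ratios
#' at the same nominal level are averaged before fitting. Linearity is
#' accepted when the determination coefficient reaches `r2_min` and the
#' residuals show no systematic sign pattern (one-sided Wald-Wolfowitz runs
#' test at alpha 0.05).
#'
#' @param nominal calibrator nominal concentrations, ng/mL, > 0; at least 3
#'   distinct levels.
#' @param ratio area ratios matching `nominal`.
#' @param blank_ratio mean area ratio of the run's blank samples (default 0).
#' @param thresholds a [threshold_config()].
#' @param weighting `"none"` (default) for unweighted OLS, or `"1/x"` for
#'   inverse-concentration weighting.
#' @param analyte optional analyte code stored on the curve.
#' @return an object of class `vams_calibration` with elements `slope`,
#'   `intercept`, `r2`, `blank_ratio`, `n_levels`, `residuals`,
#'   `pattern_flag`, `linear_ok`.
#' @export
#' @examples
#' conc <- c(1, 2, 5, 10, 20, 50)
#' fit_calibration(conc, 0.02 * conc)$slope   # 0.02
fit_calibration <- function(nominal, ratio, blank_ratio = 0,
                            thresholds = threshold_config(),
                            weighting = c("none", "1/x"),
                            analyte = NA_character_) {
  weighting <- match.arg(weighting)
  stopifnot(length(nominal) == length(ratio), inherits(thresholds, "threshold_config"))
  if (!is.numeric(nominal) || anyNA(nominal) || any(nominal <= 0)) {
    stop("calibrator nominal concentrations must be > 0 (the blank enters via blank_ratio)",
         call. = FALSE)
  }
  if (!is_scalar_number(blank_ratio) || blank_ratio < 0) {
    stop("blank_ratio must be a single value >= 0", call. = FALSE)
  }
  levels <- sort(unique(nominal))
  if (length(levels) < 3L) {
    stop("at least 3 distinct calibrator levels are required", call. = FALSE)
  }
  y <- vapply(levels, function(l) mean(ratio[nominal == l]), numeric(1)) - blank_ratio
  # linearity diagnostics (R2, residual pattern) always come from the
  # ordinary least-squares fit of the corrected points — the conventional
  # linearity assessment — even when quantification uses a weighted fit
  ols <- stats::lm(y ~ levels)
  res <- stats::residuals(ols)
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  pattern_flag <- sign_runs_pvalue(res) < 0.05
  fit <- if (weighting == "1/x") stats::lm(y ~ levels, weights = 1 / levels) else ols
  slope <- unname(stats::coef(fit)[2])
  curve <- structure(
    list(analyte = analyte, slope = slope,
         intercept = unname(stats::coef(fit)[1]), r2 = r2,
         blank_ratio = blank_ratio, n_levels = length(levels),
         residuals = unname(res), pattern_flag = pattern_flag,
         linear_ok = (r2 >= thresholds$r2_min) && !pattern_flag && slope > 0,
         weighting = weighting),
    class = "vams_calibration"
  )
  curve
}

#' @export
print.vams_calibration <- function(x, ...) {
  cat(sprintf("<vams_calibration> %s: ratio = %.6g + %.6g * conc (blank ratio %.6g)\n",
              x$analyte, x$intercept, x$slope, x$blank_ratio))
  cat(sprintf("  R2 = %.5f over %d levels; %s\n", x$r2, x$n_levels,
              if (x$linear_ok) "accepted" else "REJECTED"))
  invisible(x)
}

#' Quantify a measurement against a calibration curve
#'
#' Back-calculates the concentration from an area ratio:
#' `conc = (ratio - blank_ratio - intercept) / slope`. The run's blank ratio
#' is subtracted from unknowns exactly as it was from the calibrators
#' (symmetric treatment). Concentrations below zero (possible for
#' blank-level samples under noise) are reported as 0 and flagged
#' `truncated`; concentrations below the analyte's limit of quantification
#' are flagged `below_loq` but still reported.
#'
#' @param ratio area ratio(s) of the unknown(s), from [area_ratio()].
#' @param curve an accepted [fit_calibration()] curve (`linear_ok` must hold).
#' @param spec the [analyte_spec()] supplying the LOQ.
#' @return a tibble with columns `conc` (ng/mL), `below_loq`, `truncated`.
#' @export
quantify <- function(ratio, curve, spec) {
  stopifnot(inherits(curve, "vams_calibration"), inherits(spec, "analyte_spec"))
  if (!isTRUE(curve$linear_ok)) {
    stop("calibration curve was rejected (linear_ok is FALSE); refusing to quantify",
         call. = FALSE)
  }
  if (curve$slope <= 0) stop("calibration slope must be > 0", call. = FALSE)
  conc <- (ratio - curve$blank_ratio - curve$intercept) / curve$slope
  truncated <- conc < 0
  conc <- pmax(conc, 0)
  tibble::tibble(conc = conc, below_loq = conc < spec$loq, truncated = truncated)
}
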