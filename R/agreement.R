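# Paired serum-vs-capillary agreement: Bland-Altman statistics with
# confidence intervals, normality screening and paired significance tests.

#' Midpoint of symmetric limits of agreement
#'
#' Limits of agreement are constructed symmetrically as bias +/- 1.96 * SD of
#' the paired differences, so their midpoint recovers the mean bias. Useful
#' as an internal-consistency check on reported agreement tables.
#'
#' @param loa_low,loa_high lower and upper 95% limits of agreement, ng/mL,
#'   with `loa_low <= loa_high`.
#' @return `(loa_low + loa_high) / 2`.
#' @export
#' @examples
#' loa_midpoint(-0.40, 0.50)   # 0.05
loa_midpoint <- function(loa_low, loa_high) {
  if (any(loa_low > loa_high)) stop("loa_low must not exceed loa_high", call. = FALSE)
  (loa_low + loa_high) / 2
}

#' Normality screen and paired significance test
#'
#' Shapiro-Wilk on the paired differences; when normality is not rejected
#' (p >= alpha) the paired two-sided t-test decides, otherwise the Wilcoxon
#' signed-rank test is used and flagged (the t-test p-value is always
#' reported alongside). All-zero differences yield p = 1 with a degenerate
#' flag; nonzero constant differences (no variance) yield p = 0.
#'
#' @param x,y paired measurements (e.g. serum and corrected capillary
#'   concentrations), equal length, n >= 3.
#' @param alpha normality screening level (default 0.05).
#' @param fallback use the Wilcoxon signed-rank test when normality is
#'   rejected (default TRUE); with `FALSE` the t-test decides regardless.
#' @return list with `shapiro_p`, `paired_p`, `test_used`, `t_p`,
#'   `wilcoxon_p`, `degenerate`.
#' @export
paired_comparison <- function(x, y, alpha = 0.05, fallback = TRUE) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("at least 3 pairs are required", call. = FALSE)
  d <- x - y
  if (all(d == 0)) {
    return(list(shapiro_p = NA_real_, paired_p = 1, test_used = "degenerate",
                t_p = 1, wilcoxon_p = 1, degenerate = TRUE))
  }
  if (stats::sd(d) == 0) {
    return(list(shapiro_p = NA_real_, paired_p = 0, test_used = "degenerate",
                t_p = 0, wilcoxon_p = NA_real_, degenerate = TRUE))
  }
  # shapiro.test is defined for 3..5000 observations; beyond that the
  # normality screen is moot (the t-test is asymptotically exact) and is
  # reported as NA
  shapiro_p <- if (length(d) <= 5000) stats::shapiro.test(d)$p.value else NA_real_
  t_p <- stats::t.test(d)$p.value
  wilcoxon_p <- suppressWarnings(stats::wilcox.test(d)$p.value)
  use_wilcoxon <- isTRUE(fallback && !is.na(shapiro_p) && shapiro_p < alpha)
  list(shapiro_p = shapiro_p,
       paired_p = if (use_wilcoxon) wilcoxon_p else t_p,
       test_used = if (use_wilcoxon) "wilcoxon" else "t",
       t_p = t_p, wilcoxon_p = wilcoxon_p, degenerate = FALSE)
}

#' Bland-Altman agreement analysis
#'
#' Computes the mean difference (bias), its SD, the 95% limits of agreement
#' `bias +/- 1.96 * sd`, and confidence intervals: for the bias
#' `bias +/- t * sd / sqrt(n)` and for each limit the standard
#' large-sample approximation `LoA +/- t * sd * sqrt(3 / n)` (t is the
#' 97.5% quantile at n - 1 degrees of freedom). Percent differences
#' (difference over the pairwise mean, times 100) are returned for
#' percentage-scale difference plots; pairs whose mean is zero are excluded
#' from the percentage series and counted in `n_pct_excluded`.
#'
#' The difference direction is fixed to `serum - vams` by default; flipping
#' the direction negates the bias and swaps/negates the limits, and leaves
#' every p-value unchanged.
#'
#' @param c_serum serum concentrations, ng/mL.
#' @param c_vams_corrected serum-equivalent capillary concentrations (from
#'   [serum_from_vams()]), same length, n >= 3.
#' @param analyte optional analyte code carried in the result.
#' @param direction `"serum_minus_vams"` (default) or `"vams_minus_serum"`.
#' @param conf confidence level for the intervals (default 0.95).
#' @return an object of class `vams_agreement` with elements `analyte`, `n`,
#'   `bias`, `sd_diff`, `loa_low`, `loa_high`, `ci_bias`, `ci_loa_low`,
#'   `ci_loa_high`, `shapiro_p`, `paired_p`, `test_used`, `pct_differences`,
#'   `n_pct_excluded` and `plot_data` (tibble: `mean`, `diff`, `pct_diff`).
#' @export
#' @examples
#' ba <- bland_altman(c(1, 2, 3), c(2, 2, 2))
#' c(ba$bias, ba$sd_diff)
bland_altman <- function(c_serum, c_vams_corrected, analyte = NA_character_,
                         direction = c("serum_minus_vams", "vams_minus_serum"),
                         conf = 0.95) {
  direction <- match.arg(direction)
  stopifnot(length(c_serum) == length(c_vams_corrected))
  n <- length(c_serum)
  if (n < 3L) stop("at least 3 pairs are required", call. = FALSE)
  d <- if (direction == "serum_minus_vams") c_serum - c_vams_corrected
       else c_vams_corrected - c_serum
  m <- (c_serum + c_vams_corrected) / 2
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  loa_low <- bias - 1.96 * sd_diff
  loa_high <- bias + 1.96 * sd_diff
  tq <- stats::qt(1 - (1 - conf) / 2, df = n - 1)
  se_bias <- sd_diff / sqrt(n)
  se_loa <- sd_diff * sqrt(3 / n)
  nonzero <- m != 0
  pct <- 100 * d[nonzero] / m[nonzero]
  cmp <- paired_comparison(c_serum, c_vams_corrected)
  structure(
    list(analyte = analyte, n = n, direction = direction,
         bias = bias, sd_diff = sd_diff,
         loa_low = loa_low, loa_high = loa_high,
         ci_bias = c(low = bias - tq * se_bias, high = bias + tq * se_bias),
         ci_loa_low = c(low = loa_low - tq * se_loa, high = loa_low + tq * se_loa),
         ci_loa_high = c(low = loa_high - tq * se_loa, high = loa_high + tq * se_loa),
         shapiro_p = cmp$shapiro_p, paired_p = cmp$paired_p,
         test_used = cmp$test_used, degenerate = cmp$degenerate,
         pct_differences = pct, n_pct_excluded = sum(!nonzero),
         plot_data = tibble::tibble(
           mean = m, diff = d,
           pct_diff = ifelse(nonzero, 100 * d / ifelse(nonzero, m, NA_real_),
                             NA_real_))),
    class = "vams_agreement"
  )
}

#' @export
print.vams_agreement <- function(x, ...) {
  cat(sprintf("<vams_agreement> %s (n = %d, %s)\n", x$analyte, x$n, x$direction))
  cat(sprintf("  bias %.4g ng/mL (SD of differences %.4g)\n", x$bias, x$sd_diff))
  cat(sprintf("  95%% LoA [%.4g, %.4g]\n", x$loa_low, x$loa_high))
  cat(sprintf("  Shapiro-Wilk p = %.3g; paired %s-test p = %.3g\n",
              x$shapiro_p %||% NA_real_, x$test_used, x$paired_p))
  invisible(x)
}
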