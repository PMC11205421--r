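# Whole-blood two-compartment model.
#
# A dried capillary microsample absorbs whole blood: a serum fraction (1 - h)
# and a red-blood-cell fraction h, where h is the hematocrit. The total
# (whole-blood) concentration is the volume-weighted mixture
#
#   c_vams = (1 - h) * c_serum + h * c_rbc
#
# with c_rbc tied to c_serum by the analyte's partition behaviour:
# c_rbc = c_serum / r for ratio-mode analytes (plasma-to-RBC ratio r), or a
# constant for fixed-mode analytes (thyroxine). At the standardization
# hematocrit of 0.40, the serum compartment is 60% of the absorbed volume
# (18 uL of a 30 uL device).

#' Red-blood-cell concentration implied by a serum concentration
#'
#' @param c_serum serum concentration(s), ng/mL, >= 0.
#' @param spec an [analyte_spec()].
#' @return RBC concentration(s), ng/mL. For ratio-mode analytes
#'   `c_serum / ratio`; for fixed-mode analytes the constant RBC level,
#'   regardless of `c_serum`.
#' @export
#' @examples
#' p <- default_panel()
#' rbc_from_serum(0.4, p[["T"]])   # 0.1
#' rbc_from_serum(84, p[["T4"]])   # 0.54
rbc_from_serum <- function(c_serum, spec) {
  stopifnot(inherits(spec, "analyte_spec"))
  check_nonneg(c_serum, "c_serum")
  if (spec$partition$mode == "ratio") {
    c_serum / spec$partition$ratio
  } else {
    rep(spec$partition$fixed_rbc_conc, length(c_serum))
  }
}

#' Whole-blood (VAMS) concentration from a serum concentration
#'
#' Volume-weighted mixture of the serum and RBC compartments at hematocrit
#' `hct`: `(1 - hct) * c_serum + hct * rbc_from_serum(c_serum, spec)`.
#'
#' @inheritParams rbc_from_serum
#' @param hct hematocrit, volume fraction in `[0, 0.95]` (default 0.40, the
#'   calibration standardization level).
#' @return total whole-blood concentration(s), ng/mL.
#' @export
#' @examples
#' vams_from_serum(1, default_panel()[["T"]], hct = 0.4)   # 0.7
vams_from_serum <- function(c_serum, spec, hct = 0.4) {
  check_hct(hct)
  check_nonneg(c_serum, "c_serum")
  (1 - hct) * c_serum + hct * rbc_from_serum(c_serum, spec)
}

#' Serum-equivalent concentration from a whole-blood (VAMS) concentration
#'
#' Inverts [vams_from_serum()]. For ratio-mode analytes the partition relation
#' `c_rbc = c_serum / r` is solved simultaneously with the mixture equation,
#' giving the closed form `c_serum = c_vams / ((1 - h) + h / r)` — exact, and
#' identical to sequential back-substitution of the 0.6/0.4 arithmetic at the
#' standardization hematocrit. For fixed-mode analytes
#' `c_serum = (c_vams - h * c_rbc) / (1 - h)`; values driven below zero by
#' measurement noise are clamped to 0 and flagged via the `"truncated"`
#' attribute rather than raising an error.
#'
#' When the partition ratio is a panel default (see [default_panel()]), the
#' result carries attribute `"defaulted_partition" = TRUE`.
#'
#' @param c_vams whole-blood concentration(s), ng/mL, >= 0.
#' @inheritParams vams_from_serum
#' @return serum-equivalent concentration(s), ng/mL, with logical attribute
#'   `"truncated"` marking clamped values.
#' @export
#' @examples
#' serum_from_vams(0.7, default_panel()[["T"]], hct = 0.4)   # 1.0
serum_from_vams <- function(c_vams, spec, hct = 0.4) {
  check_hct(hct)
  check_nonneg(c_vams, "c_vams")
  if (spec$partition$mode == "ratio") {
    out <- c_vams / ((1 - hct) + hct / spec$partition$ratio)
    truncated <- rep(FALSE, length(out))
  } else {
    raw <- (c_vams - hct * spec$partition$fixed_rbc_conc) / (1 - hct)
    truncated <- raw < 0
    out <- pmax(raw, 0)
  }
  attr(out, "truncated") <- truncated
  if (spec$partition$defaulted) attr(out, "defaulted_partition") <- TRUE
  out
}

#' Predicted hematocrit bias profile
#'
#' A method calibrated at a reference hematocrit systematically mis-measures
#' samples drawn at other hematocrits, because the whole-blood concentration
#' of a partitioning analyte depends on the serum/RBC volume split. This
#' function computes the predicted relative deviation
#' `100 * (c_vams(h) / c_vams(ref_hct) - 1)` over a hematocrit grid, and the
#' contiguous sub-range around the reference within the acceptance band.
#'
#' For ratio-mode analytes the profile is independent of the test
#' concentration (the model is linear in `c_serum`); this is asserted
#' internally at three concentrations spanning the working range. Fixed-mode
#' analytes require a `conc` at which to evaluate the profile.
#'
#' @param spec an [analyte_spec()].
#' @param hct_grid hematocrit values, each in `[0, 0.95]`; the reference is
#'   inserted if absent.
#' @param ref_hct reference (calibration standardization) hematocrit.
#' @param conc serum concentration at which to evaluate a fixed-mode profile;
#'   ignored for ratio-mode analytes.
#' @param thresholds a [threshold_config()]; `hct_dev_max_pct` defines the
#'   acceptance band.
#' @return a tibble with columns `hct` and `deviation_pct`, plus attribute
#'   `"pass_range"`: the `(low, high)` endpoints of the maximal contiguous
#'   grid sub-range containing `ref_hct` with `|deviation| <= hct_dev_max_pct`.
#' @export
#' @examples
#' prof <- hct_bias_profile(default_panel()[["T"]], seq(0.3, 0.5, 0.05))
#' attr(prof, "pass_range")
hct_bias_profile <- function(spec, hct_grid = seq(0.30, 0.70, by = 0.05),
                             ref_hct = 0.4, conc = NULL,
                             thresholds = threshold_config()) {
  stopifnot(inherits(spec, "analyte_spec"), inherits(thresholds, "threshold_config"))
  if (length(hct_grid) == 0) stop("hct_grid must not be empty", call. = FALSE)
  check_hct(hct_grid)
  check_hct(ref_hct)
  grid <- sort(unique(c(hct_grid, ref_hct)))
  if (spec$partition$mode == "ratio") {
    test_conc <- c(0.01, 1, 1000)
    devs <- vapply(test_conc, function(cc) {
      100 * (vams_from_serum(cc, spec, grid) / vams_from_serum(cc, spec, ref_hct) - 1)
    }, numeric(length(grid)))
    devs <- matrix(devs, nrow = length(grid))
    if (max(abs(devs - devs[, 1])) > 1e-9) {
      stop("internal error: ratio-mode bias profile depends on concentration")
    }
    deviation <- devs[, 1]
  } else {
    if (!is_scalar_number(conc) || conc <= 0) {
      stop("fixed-mode analytes need a positive 'conc' to evaluate the profile",
           call. = FALSE)
    }
    deviation <- 100 * (vams_from_serum(conc, spec, grid) /
                          vams_from_serum(conc, spec, ref_hct) - 1)
  }
  ok <- abs(deviation) <= thresholds$hct_dev_max_pct
  i_ref <- which(grid == ref_hct)
  lo <- i_ref
  while (lo > 1 && ok[lo - 1]) lo <- lo - 1
  hi <- i_ref
  while (hi < length(grid) && ok[hi + 1]) hi <- hi + 1
  out <- tibble::tibble(hct = grid, deviation_pct = deviation)
  attr(out, "pass_range") <- c(low = grid[lo], high = grid[hi])
  out
}
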