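# Analyte panel: per-hormone constants and acceptance thresholds.
#
# The panel is the single source of truth for every other module: partition
# behaviour between serum and red blood cells, limits of quantification,
# calibration ranges, internal-standard assignments and residual endogenous
# levels in the surrogate blank matrix.

#' Partition behaviour of an analyte between serum and red blood cells
#'
#' Two modes exist. `"ratio"` analytes equilibrate with a fixed
#' plasma-to-RBC concentration ratio (e.g. 4:1 for testosterone), so the RBC
#' concentration scales with the serum concentration. `"fixed"` analytes
#' (thyroxine) carry an essentially constant RBC concentration independent of
#' the serum level.
#'
#' @param mode `"ratio"` or `"fixed"`.
#' @param ratio plasma-to-RBC concentration ratio, dimensionless, > 0.
#'   Only for `mode = "ratio"`.
#' @param fixed_rbc_conc constant RBC concentration in ng/mL, >= 0. Only for
#'   `mode = "fixed"`.
#' @param defaulted set `TRUE` when the ratio is a panel default rather than a
#'   literature value; conversions propagate this as a warning flag so that
#'   results based on an assumed partition are never silently reported.
#' @return an object of class `partition_spec`.
#' @export
#' @examples
#' partition_spec("ratio", ratio = 4)
#' partition_spec("fixed", fixed_rbc_conc = 0.54)
partition_spec <- function(mode = c("ratio", "fixed"), ratio = NULL,
                           fixed_rbc_conc = NULL, defaulted = FALSE) {
  mode <- match.arg(mode)
  if (mode == "ratio") {
    if (!is.null(fixed_rbc_conc)) {
      stop("partition mode 'ratio': 'fixed_rbc_conc' must not be set", call. = FALSE)
    }
    if (!is_scalar_number(ratio) || ratio <= 0) {
      stop("plasma_to_rbc_ratio must be > 0", call. = FALSE)
    }
    fixed_rbc_conc <- NA_real_
  } else {
    if (!is.null(ratio)) {
      stop("partition mode 'fixed': 'ratio' must not be set", call. = FALSE)
    }
    if (!is_scalar_number(fixed_rbc_conc) || fixed_rbc_conc < 0) {
      stop("fixed_rbc_conc must be >= 0", call. = FALSE)
    }
    ratio <- NA_real_
  }
  structure(
    list(mode = mode, ratio = as.numeric(ratio),
         fixed_rbc_conc = as.numeric(fixed_rbc_conc),
         defaulted = isTRUE(defaulted)),
    class = "partition_spec"
  )
}

#' @export
print.partition_spec <- function(x, ...) {
  if (x$mode == "ratio") {
    cat(sprintf("plasma-to-RBC ratio %g:1%s\n", x$ratio,
                if (x$defaulted) " (panel default, not a literature value)" else ""))
  } else {
    cat(sprintf("fixed RBC concentration %g ng/mL\n", x$fixed_rbc_conc))
  }
  invisible(x)
}

#' One hormone of the assay panel
#'
#' Bundles the constants quantification needs: partition behaviour, limit of
#' quantification, calibration range, the assigned internal standard and the
#' residual endogenous concentration expected in the surrogate "blank" matrix
#' (washed red blood cells in albumin are never perfectly hormone-free).
#' All concentrations are ng/mL.
#'
#' @param name full analyte name.
#' @param short_code compact code used as the `analyte` key in tables
#'   (e.g. `"T"`, `"A4"`, `"DHEA-S"`).
#' @param partition a [partition_spec()].
#' @param loq limit of quantification, ng/mL, > 0.
#' @param calibration_range numeric length-2 `(low, high)` ng/mL with
#'   `low < high` and `loq <= high`.
#' @param istd_name stable-isotope-labelled internal standard.
#' @param blank_residual residual endogenous level in blank matrix, ng/mL.
#' @param ms_meta optional list of instrument metadata (precursor_mz,
#'   quantifier_mz, qualifier_mz, rt_min, ce_ev); documentation only, never
#'   used in computation.
#' @return an object of class `analyte_spec`.
#' @export
analyte_spec <- function(name, short_code, partition, loq, calibration_range,
                         istd_name, blank_residual = 0, ms_meta = NULL) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(short_code), length(short_code) == 1L,
            inherits(partition, "partition_spec"))
  if (!is_scalar_number(loq) || loq <= 0) {
    stop("loq must be > 0", call. = FALSE)
  }
  if (!is.numeric(calibration_range) || length(calibration_range) != 2L ||
      anyNA(calibration_range) || calibration_range[1] >= calibration_range[2]) {
    stop("calibration_range must be (low, high) with low < high", call. = FALSE)
  }
  if (loq > calibration_range[2]) {
    stop("loq must not exceed the upper calibration limit", call. = FALSE)
  }
  if (!is_scalar_number(blank_residual) || blank_residual < 0) {
    stop("blank_residual must be >= 0", call. = FALSE)
  }
  if (!is.null(ms_meta)) {
    allowed <- c("precursor_mz", "quantifier_mz", "qualifier_mz", "rt_min", "ce_ev")
    bad <- setdiff(names(ms_meta), allowed)
    if (length(bad)) {
      stop("unknown ms_meta field(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  structure(
    list(name = name, short_code = short_code, partition = partition,
         loq = as.numeric(loq),
         calibration_range = as.numeric(unname(calibration_range)),
         istd_name = istd_name, blank_residual = as.numeric(blank_residual),
         ms_meta = ms_meta),
    class = "analyte_spec"
  )
}

#' @export
print.analyte_spec <- function(x, ...) {
  cat(sprintf("<analyte_spec> %s (%s)\n", x$name, x$short_code))
  cat("  partition: "); print(x$partition)
  cat(sprintf("  LOQ %g ng/mL, calibration %g-%g ng/mL, ISTD %s\n",
              x$loq, x$calibration_range[1], x$calibration_range[2], x$istd_name))
  if (x$blank_residual > 0) {
    cat(sprintf("  blank matrix residual %g ng/mL\n", x$blank_residual))
  }
  invisible(x)
}

#' Acceptance thresholds for method validation
#'
#' FDA-style bioanalytical acceptance criteria applied by the validation
#' module. All values are strictly positive; percentages are on the 0-100
#' scale.
#'
#' @param cv_max_pct maximum acceptable intraday/interday CV (default 15).
#' @param accuracy_tol_pct maximum deviation of accuracy from 100% (default 15).
#' @param loq_cv_max_pct maximum CV at the limit of quantification (default 20).
#' @param loq_min_snr minimum mean signal-to-noise ratio at the LOQ (default 10).
#' @param stability_tol_pct maximum concentration drift from day 0 (default 15).
#' @param hct_dev_max_pct maximum concentration deviation from the hematocrit
#'   standardization level (default 20).
#' @param carryover_max_pct maximum blank-after-high signal as percent of the
#'   high sample (default 0.01).
#' @param r2_min minimum calibration determination coefficient (default 0.99).
#' @return an object of class `threshold_config`.
#' @export
threshold_config <- function(cv_max_pct = 15, accuracy_tol_pct = 15,
                             loq_cv_max_pct = 20, loq_min_snr = 10,
                             stability_tol_pct = 15, hct_dev_max_pct = 20,
                             carryover_max_pct = 0.01, r2_min = 0.99) {
  vals <- list(cv_max_pct = cv_max_pct, accuracy_tol_pct = accuracy_tol_pct,
               loq_cv_max_pct = loq_cv_max_pct, loq_min_snr = loq_min_snr,
               stability_tol_pct = stability_tol_pct,
               hct_dev_max_pct = hct_dev_max_pct,
               carryover_max_pct = carryover_max_pct, r2_min = r2_min)
  for (nm in names(vals)) {
    if (!is_scalar_number(vals[[nm]]) || vals[[nm]] <= 0) {
      stop(nm, " must be a positive number", call. = FALSE)
    }
  }
  if (r2_min >= 1) stop("r2_min must be < 1", call. = FALSE)
  structure(vals, class = "threshold_config")
}

as_panel <- function(specs) {
  stopifnot(all(vapply(specs, inherits, logical(1), "analyte_spec")))
  codes <- vapply(specs, `[[`, character(1), "short_code")
  if (anyDuplicated(codes)) {
    stop("duplicate analyte code: ",
         paste(unique(codes[duplicated(codes)]), collapse = ", "), call. = FALSE)
  }
  names(specs) <- codes
  structure(specs, class = "vams_panel")
}

#' @export
print.vams_panel <- function(x, ...) {
  cat(sprintf("<vams_panel> %d analytes: %s\n", length(x),
              paste(names(x), collapse = ", ")))
  invisible(x)
}

#' The default eight-hormone assay panel
#'
#' Steroids and thyroid hormones with their partition behaviour, limits of
#' quantification and calibration ranges. Partition ratios: 4:1 for the
#' steroids A4, DHEA-S and T, 5:1 for cortisol, 3.2:1 for T3, and a fixed RBC
#' concentration of 0.54 ng/mL (the mean of the reported 0.30-0.78 ng/mL
#' range) for T4. Progesterone and estradiol have no established partition
#' ratio; the panel applies the 4:1 steroid default and marks it `defaulted`
#' so downstream serum conversions carry a warning flag.
#'
#' Residual endogenous concentrations in the surrogate blank matrix are
#' 45 ng/mL for DHEA-S, 0.001 ng/mL for T and 0.15 ng/mL for T4
#' (zero for the rest); calibration handles these by run-level blank
#' correction.
#'
#' @return a `vams_panel`: named list of [analyte_spec()] objects, keyed by
#'   short code (`A4`, `F`, `DHEA-S`, `P4`, `T`, `T3`, `T4`, `E2`).
#' @export
#' @examples
#' panel <- default_panel()
#' panel[["T"]]$partition$ratio
#' panel[["T4"]]$partition$fixed_rbc_conc
default_panel <- function() {
  as_panel(list(
    analyte_spec("4-Androstenedione", "A4",
                 partition_spec("ratio", ratio = 4),
                 loq = 0.5, calibration_range = c(0.5, 10),
                 istd_name = "testosterone-d3",
                 ms_meta = list(precursor_mz = 287.2011, quantifier_mz = 97.07,
                                qualifier_mz = 109.06, rt_min = 8.36, ce_ev = 30)),
    analyte_spec("Cortisol", "F",
                 partition_spec("ratio", ratio = 5),
                 loq = 2.5, calibration_range = c(2.5, 250),
                 istd_name = "cortisol-d4",
                 ms_meta = list(precursor_mz = 363.2171, quantifier_mz = 121.07,
                                qualifier_mz = 327.20, rt_min = 7.45, ce_ev = 25)),
    analyte_spec("Dehydroepiandrosterone sulfate", "DHEA-S",
                 partition_spec("ratio", ratio = 4),
                 loq = 2.5, calibration_range = c(2.5, 5000),
                 istd_name = "testosterone-d3", blank_residual = 45,
                 ms_meta = list(precursor_mz = 367.1578, quantifier_mz = 96.96,
                                rt_min = 8.22, ce_ev = 35)),
    analyte_spec("Progesterone", "P4",
                 partition_spec("ratio", ratio = 4, defaulted = TRUE),
                 loq = 0.8, calibration_range = c(0.8, 40),
                 istd_name = "progesterone-d9",
                 ms_meta = list(precursor_mz = 315.2324, quantifier_mz = 109.06,
                                qualifier_mz = 97.06, rt_min = 9.36, ce_ev = 20)),
    analyte_spec("Testosterone", "T",
                 partition_spec("ratio", ratio = 4),
                 loq = 0.02, calibration_range = c(0.02, 16),
                 istd_name = "testosterone-d3", blank_residual = 0.001,
                 ms_meta = list(precursor_mz = 289.2167, quantifier_mz = 97.07,
                                qualifier_mz = 109.06, rt_min = 8.64, ce_ev = 25)),
    analyte_spec("Triiodothyronine", "T3",
                 partition_spec("ratio", ratio = 3.2),
                 loq = 0.1, calibration_range = c(0.1, 4),
                 istd_name = "triiodothyronine-13C6",
                 ms_meta = list(precursor_mz = 651.7978, quantifier_mz = 605.79,
                                qualifier_mz = 507.87, rt_min = 7.83, ce_ev = 20)),
    analyte_spec("Thyroxine", "T4",
                 partition_spec("fixed", fixed_rbc_conc = 0.54),
                 loq = 0.5, calibration_range = c(0.5, 160),
                 istd_name = "thyroxine-13C6", blank_residual = 0.15,
                 ms_meta = list(precursor_mz = 777.6866, quantifier_mz = 731.69,
                                qualifier_mz = 633.76, rt_min = 8.37, ce_ev = 25)),
    analyte_spec("17beta-Estradiol", "E2",
                 partition_spec("ratio", ratio = 4, defaulted = TRUE),
                 loq = 0.04, calibration_range = c(0.04, 4),
                 istd_name = "estradiol-d4",
                 ms_meta = list(precursor_mz = 431.1926, quantifier_mz = 367.2,
                                rt_min = 9.26, ce_ev = 50))
  ))
}

panel_to_list <- function(panel) {
  lapply(unname(panel), function(s) {
    part <- list(mode = s$partition$mode,
                 value = if (s$partition$mode == "ratio") s$partition$ratio
                         else s$partition$fixed_rbc_conc)
    if (s$partition$defaulted) part$defaulted <- TRUE
    out <- list(name = s$name, short_code = s$short_code, partition = part,
                loq = s$loq,
                calibration_range = list(low = s$calibration_range[1],
                                         high = s$calibration_range[2]),
                istd_name = s$istd_name, blank_residual = s$blank_residual)
    if (!is.null(s$ms_meta)) out$ms_meta <- s$ms_meta
    out
  })
}

#' Write a panel configuration to YAML
#'
#' @param panel a `vams_panel`.
#' @param path output file.
#' @return `path`, invisibly.
#' @seealso [load_panel()]
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "vams_panel"))
  yaml::write_yaml(panel_to_list(panel), path, precision = 15)
  invisible(path)
}

parse_partition <- function(p, where) {
  if (!is.list(p)) stop(where, ": partition must be a mapping", call. = FALSE)
  allowed <- c("mode", "value", "plasma_to_rbc_ratio", "fixed_rbc_conc", "defaulted")
  bad <- setdiff(names(p), allowed)
  if (length(bad)) {
    stop(where, ": unknown partition field(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.null(p$plasma_to_rbc_ratio) && !is.null(p$fixed_rbc_conc)) {
    stop(where, ": partition must not set both plasma_to_rbc_ratio and fixed_rbc_conc",
         call. = FALSE)
  }
  mode <- p$mode %||%
    if (!is.null(p$fixed_rbc_conc)) "fixed" else "ratio"
  if (!mode %in% c("ratio", "fixed")) {
    stop(where, ": partition mode must be 'ratio' or 'fixed'", call. = FALSE)
  }
  value <- p$value %||% p$plasma_to_rbc_ratio %||% p$fixed_rbc_conc
  if (is.null(value)) stop(where, ": partition value missing", call. = FALSE)
  if (mode == "ratio") {
    if (!is_scalar_number(value) || value <= 0) {
      stop(where, ": plasma_to_rbc_ratio must be > 0", call. = FALSE)
    }
    partition_spec("ratio", ratio = value, defaulted = isTRUE(p$defaulted))
  } else {
    partition_spec("fixed", fixed_rbc_conc = value, defaulted = isTRUE(p$defaulted))
  }
}

#' Load a panel configuration
#'
#' Reads a YAML document whose top level is a list of analyte records with the
#' field names of [analyte_spec()] and the partition given as
#' `{mode, value}`. Unknown fields and duplicate analyte codes are rejected;
#' every analyte invariant is enforced on load.
#'
#' @param x path to a YAML file, or an already-parsed list.
#' @return a `vams_panel`.
#' @export
load_panel <- function(x) {
  doc <- if (is.character(x) && length(x) == 1L) yaml::read_yaml(x) else x
  if (!is.list(doc) || length(doc) == 0) {
    stop("panel config must be a non-empty list of analyte records", call. = FALSE)
  }
  allowed <- c("name", "short_code", "partition", "loq", "calibration_range",
               "istd_name", "blank_residual", "ms_meta")
  specs <- lapply(seq_along(doc), function(i) {
    rec <- doc[[i]]
    where <- sprintf("analyte record %d (%s)", i, rec$short_code %||% "?")
    bad <- setdiff(names(rec), allowed)
    if (length(bad)) {
      stop(where, ": unknown field(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    for (f in c("name", "short_code", "partition", "loq", "calibration_range",
                "istd_name")) {
      if (is.null(rec[[f]])) stop(where, ": missing field '", f, "'", call. = FALSE)
    }
    cr <- rec$calibration_range
    cr <- if (is.list(cr)) c(cr$low, cr$high) else as.numeric(cr)
    analyte_spec(rec$name, rec$short_code, parse_partition(rec$partition, where),
                 loq = rec$loq, calibration_range = cr,
                 istd_name = rec$istd_name,
                 blank_residual = rec$blank_residual %||% 0,
                 ms_meta = rec$ms_meta)
  })
  as_panel(specs)
}
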