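# Batch processing: per-run calibration, table-level quantification, and the
# full validation analysis of a simulated or imported batch.

check_peak_table <- function(tbl) {
  missing <- setdiff(peak_table_cols, names(tbl))
  if (length(missing)) {
    stop("peak table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(tbl)
}

#' Fit run-level calibration curves for every analyte in a peak table
#'
#' For each (analyte, run) pair present, averages the duplicate blank area
#' ratios into the run's blank ratio and fits the blank-corrected curve from
#' the run's calibrator rows.
#'
#' @param tbl a peak table (see [read_peak_table()] for the layout).
#' @param panel a `vams_panel` covering every analyte in the table.
#' @param thresholds a [threshold_config()].
#' @param weighting passed to [fit_calibration()]. The pipeline default is
#'   `"1/x"`: over a calibration range spanning orders of magnitude with
#'   relative (multiplicative) noise, the unweighted intercept's sampling
#'   error in concentration units can exceed the limit of quantification,
#'   corrupting every low-end result; inverse-concentration weighting anchors
#'   the intercept at the bottom of the range.
#' @return a named list of `vams_calibration` objects keyed `"analyte|run"`.
#' @export
calibrate_runs <- function(tbl, panel, thresholds = threshold_config(),
                           weighting = "1/x") {
  check_peak_table(tbl)
  cal <- tbl[tbl$role == "calibrator", ]
  if (nrow(cal) == 0) stop("no calibrator rows in the peak table", call. = FALSE)
  curves <- list()
  for (key in unique(paste(cal$analyte, cal$run_id, sep = "|"))) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    a <- parts[1]; r <- parts[2]
    spec <- panel[[a]]
    if (is.null(spec)) stop("analyte not in panel: ", a, call. = FALSE)
    cc <- cal[cal$analyte == a & cal$run_id == r, ]
    bb <- tbl[tbl$analyte == a & tbl$run_id == r & tbl$role == "blank" &
                grepl("^BLK", tbl$sample_id), ]
    blank_ratio <- if (nrow(bb)) {
      mean(area_ratio(bb$analyte_area, bb$istd_area, bb$sample_id))
    } else 0
    curves[[key]] <- fit_calibration(
      cc$nominal_conc, area_ratio(cc$analyte_area, cc$istd_area, cc$sample_id),
      blank_ratio = blank_ratio, thresholds = thresholds,
      weighting = weighting, analyte = a)
  }
  curves
}

#' Quantify every QC/sample row of a peak table
#'
#' Applies the run's calibration to each row with role `qc` or `sample`, and
#' optionally converts the whole-blood concentration to its serum equivalent
#' through the compartment model.
#'
#' @inheritParams calibrate_runs
#' @param curves optional pre-fitted output of [calibrate_runs()].
#' @param to_serum also report serum-equivalent concentrations.
#' @param hct hematocrit for the serum conversion when a row has none in its
#'   `hct` column; required (error otherwise) if `to_serum = TRUE` and any
#'   row lacks one.
#' Rows whose run calibration was rejected (`linear_ok` FALSE) are returned
#' with `conc = NA` under a warning naming the affected analyte/run pairs —
#' a single failed curve does not abort a batch. ([quantify()] itself stays
#' strict.)
#'
#' @return the quantified rows with added columns `conc`, `below_loq`,
#'   `truncated` and, with `to_serum`, `c_serum_eq`.
#' @export
quantify_batch <- function(tbl, panel, thresholds = threshold_config(),
                           curves = NULL, to_serum = FALSE, hct = NULL) {
  check_peak_table(tbl)
  if (is.null(curves)) curves <- calibrate_runs(tbl, panel, thresholds)
  rows <- tbl[tbl$role %in% c("qc", "sample"), ]
  key <- paste(rows$analyte, rows$run_id, sep = "|")
  missing <- setdiff(unique(key), names(curves))
  if (length(missing)) {
    stop("no calibration available for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  conc <- rep(NA_real_, nrow(rows))
  below <- rep(NA, nrow(rows))
  trunc <- rep(NA, nrow(rows))
  rejected <- character(0)
  for (k in unique(key)) {
    idx <- key == k
    a <- strsplit(k, "|", fixed = TRUE)[[1]][1]
    if (!isTRUE(curves[[k]]$linear_ok)) {
      rejected <- c(rejected, k)
      next
    }
    q <- quantify(area_ratio(rows$analyte_area[idx], rows$istd_area[idx],
                             rows$sample_id[idx]),
                  curves[[k]], panel[[a]])
    conc[idx] <- q$conc
    below[idx] <- q$below_loq
    trunc[idx] <- q$truncated
  }
  if (length(rejected)) {
    warning("calibration rejected, rows left unquantified (NA) for: ",
            paste(rejected, collapse = ", "), call. = FALSE)
  }
  rows$conc <- conc
  rows$below_loq <- below
  rows$truncated <- trunc
  if (to_serum) {
    h <- rows$hct
    if (anyNA(h)) {
      if (is.null(hct)) {
        stop("serum conversion requested but some rows have no hematocrit; ",
             "supply 'hct' or fill the hct column", call. = FALSE)
      }
      h[is.na(h)] <- hct
    }
    rows$c_serum_eq <- vapply(seq_len(nrow(rows)), function(i) {
      if (is.na(rows$conc[i])) return(NA_real_)
      as.numeric(serum_from_vams(rows$conc[i], panel[[rows$analyte[i]]], h[i]))
    }, numeric(1))
  }
  rows
}

#' Run the full validation battery on a simulated or imported batch
#'
#' Consumes a peak table in the layout written by
#' [simulate_validation_batch()] (experiment membership encoded in the
#' `sample_id` prefixes) and computes, per analyte: run calibrations,
#' intra/interday imprecision on the QC area ratios, accuracy of the
#' back-calculated QC concentrations, the limit of quantification from the
#' level sets, extraction recovery and matrix effect from the raw area sets,
#' carryover, the hematocrit robustness profile (concentrations
#' serum-converted at the assumed standardization hematocrit) and the
#' storage-stability series per temperature.
#'
#' @inheritParams calibrate_runs
#' @param ref_hct the standardization hematocrit used for the robustness
#'   normalization.
#' @return a list with one [validation_report()] per analyte plus
#'   `overall_pass` (conjunction over analytes).
#' @export
analyze_validation_batch <- function(tbl, panel, thresholds = threshold_config(),
                                     ref_hct = 0.4) {
  check_peak_table(tbl)
  curves <- calibrate_runs(tbl, panel, thresholds)
  reports <- list()
  for (code in intersect(names(panel), unique(tbl$analyte))) {
    spec <- panel[[code]]
    at <- tbl[tbl$analyte == code, ]
    a_curves <- curves[grep(paste0("^", code, "\\|"), names(curves))]
    r1 <- curves[[paste(code, "R1", sep = "|")]]
    # a rejected curve fails the linearity gate and leaves the components
    # that depend on it unassessed, rather than aborting the whole batch
    try_quantify <- function(rows, curve) {
      tryCatch(quantify(area_ratio(rows$analyte_area, rows$istd_area,
                                   rows$sample_id), curve, spec),
               error = function(e) NULL)
    }

    prec_rows <- at[grepl("^PREC_", at$sample_id), ]
    prec <- acc <- NULL
    if (nrow(prec_rows)) {
      prec <- imprecision(area_ratio(prec_rows$analyte_area, prec_rows$istd_area),
                          prec_rows$run_id, thresholds)
      qconc <- unlist(lapply(unique(prec_rows$run_id), function(r) {
        q <- try_quantify(prec_rows[prec_rows$run_id == r, ],
                          curves[[paste(code, r, sep = "|")]])
        if (is.null(q)) NULL else q$conc
      }))
      if (length(qconc) == nrow(prec_rows)) {
        acc <- accuracy(qconc, prec_rows$nominal_conc[1], thresholds)
      }
    }

    # LOQ from replicate response CVs (area ratios, as for imprecision) and
    # the mean SNR per level: back-calculation through the curve would fold
    # intercept sampling noise into every low level
    loq_rows <- at[grepl("^LOQ_", at$sample_id), ]
    loq <- NULL
    if (nrow(loq_rows)) {
      rat <- area_ratio(loq_rows$analyte_area, loq_rows$istd_area,
                        loq_rows$sample_id)
      loq <- estimate_loq(
        loq_level_summary(loq_rows$nominal_conc, rat, loq_rows$snr),
        thresholds)
    }

    rec_pct <- me_pct <- NULL
    pre <- at$analyte_area[grepl("^REC_PRE_", at$sample_id)]
    post <- at$analyte_area[grepl("^REC_POST_", at$sample_id)]
    if (length(pre) && length(post)) rec_pct <- recovery(pre, post)
    mat <- at$analyte_area[grepl("^ME_MAT_", at$sample_id)]
    sol <- at$analyte_area[grepl("^ME_SOL_", at$sample_id)]
    if (length(mat) && length(sol)) me_pct <- matrix_effect(mat, sol)

    co <- NULL
    high <- at$analyte_area[at$sample_id == "CARRY_HIGH"]
    blk1 <- at$analyte_area[at$sample_id == "CARRY_BLK1"]
    if (length(high) == 1L && length(blk1) == 1L) {
      co <- carryover(blk1, high, thresholds)
    }

    hct_rows <- at[grepl("^HCT_", at$sample_id), ]
    hct_res <- NULL
    if (nrow(hct_rows)) {
      q <- try_quantify(hct_rows, r1)
      if (!is.null(q)) {
        serum_eq <- as.numeric(serum_from_vams(q$conc, spec, ref_hct))
        hct_res <- hct_robustness(hct_rows$hct, serum_eq, ref_hct, thresholds)
      }
    }

    stab_rows <- at[grepl("^STAB_", at$sample_id), ]
    stab <- NULL
    if (nrow(stab_rows)) {
      stab <- lapply(unique(stab_rows$storage_temp_c), function(tc) {
        sr <- stab_rows[stab_rows$storage_temp_c == tc, ]
        q <- try_quantify(sr, r1)
        if (is.null(q)) return(NULL)
        stability_assess(sr$storage_days, q$conc, temp_c = tc, thresholds)
      })
      stab <- Filter(Negate(is.null), stab)
      if (!length(stab)) stab <- NULL
    }

    reports[[code]] <- suppressWarnings(validation_report(
      code, precision = prec, accuracy_result = acc, calibration = a_curves,
      loq = loq, recovery_pct = rec_pct, matrix_effect_pct = me_pct,
      carryover_result = co, hct = hct_res, stability = stab,
      thresholds = thresholds))
  }
  list(analytes = reports,
       overall_pass = all(vapply(reports, `[[`, logical(1), "overall_pass")))
}
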