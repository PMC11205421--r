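# File interchange: the strict peak-table CSV dialect, paired-study tables,
# and JSON reports with an embedded run manifest.

peak_roles <- c("blank", "calibrator", "qc", "sample")

#' Read a peak table from delimited text
#'
#' The dialect is strict: UTF-8, `.` decimal, header exactly
#' `sample_id, analyte, role, run_id, day_index, analyte_area, istd_area,
#' snr, nominal_conc, hct, storage_days, storage_temp_c` (trailing optional
#' columns may be empty). Character fields are whitespace-trimmed; the role
#' is validated against the role enum. A zero internal-standard area parses
#' — the error is raised where it matters, at [area_ratio()] time, with the
#' offending sample named.
#'
#' @param path input file.
#' @param delimiter field separator (default comma).
#' @return a peak table tibble.
#' @export
read_peak_table <- function(path, delimiter = ",") {
  raw <- utils::read.table(path, sep = delimiter, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           strip.white = TRUE, blank.lines.skip = TRUE,
                           quote = "\"", comment.char = "")
  missing <- setdiff(peak_table_cols, names(raw))
  if (length(missing)) {
    stop("peak table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  raw <- raw[peak_table_cols]
  num_cols <- c("day_index", "analyte_area", "istd_area", "snr", "nominal_conc",
                "hct", "storage_days", "storage_temp_c")
  for (col in num_cols) {
    v <- trimws(raw[[col]])
    v[v == ""] <- NA
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad)) {
      stop(sprintf("non-numeric value '%s' in column '%s' at data row %d",
                   v[bad[1]], col, bad[1]), call. = FALSE)
    }
    raw[[col]] <- num
  }
  for (col in c("sample_id", "analyte", "role", "run_id")) {
    raw[[col]] <- trimws(raw[[col]])
  }
  bad_role <- setdiff(unique(raw$role), peak_roles)
  if (length(bad_role)) {
    stop("unknown role(s): ", paste(bad_role, collapse = ", "),
         "; expected one of ", paste(peak_roles, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(raw)
}

#' Write a peak table to delimited text
#'
#' Numeric values are written at full double precision so that a write/read
#' round trip is lossless.
#'
#' @param tbl a peak table.
#' @param path output file.
#' @param delimiter field separator.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(tbl, path, delimiter = ",") {
  check_peak_table(tbl)
  out <- as.data.frame(tbl)[peak_table_cols]
  for (col in names(out)) {
    if (is.numeric(out[[col]])) {
      out[[col]] <- ifelse(is.na(out[[col]]), "",
                           format(out[[col]], digits = 17, trim = TRUE,
                                  scientific = FALSE))
    }
  }
  utils::write.table(out, path, sep = delimiter, row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' Read a paired serum/capillary concentration table
#'
#' Columns: `subject_id, analyte, c_serum, c_vams` (whole-blood or already
#' serum-corrected, per the caller's convention).
#'
#' @inheritParams read_peak_table
#' @return a tibble.
#' @export
read_paired_table <- function(path, delimiter = ",") {
  raw <- utils::read.table(path, sep = delimiter, header = TRUE,
                           strip.white = TRUE, quote = "\"", comment.char = "")
  need <- c("subject_id", "analyte", "c_serum", "c_vams")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    stop("paired table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tibble::as_tibble(raw[need])
}

#' Run manifest for reproducible reports
#'
#' Every JSON report embeds one of these: the command, configuration and
#' input paths, the seed of any stochastic step, a timestamp and the package
#' version — enough to regenerate the artifact byte-for-byte (modulo the
#' timestamp) with the same package version.
#'
#' @param command the operation that produced the report.
#' @param config_path,inputs provenance paths.
#' @param seed RNG seed used (NA for deterministic commands).
#' @return a named list.
#' @export
run_manifest <- function(command, config_path = NA_character_,
                         inputs = character(), seed = NA_integer_) {
  list(command = command, config_path = config_path, inputs = inputs,
       seed = seed, timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       package_version = as.character(utils::packageVersion("vamsquant")))
}

strip_for_json <- function(x) {
  if (inherits(x, "tbl_df")) return(as.data.frame(x))
  if (is.list(x)) {
    x <- lapply(x, strip_for_json)
    attributes(x) <- list(names = names(x))
    return(x)
  }
  if (is.numeric(x) && any(is.infinite(x))) {
    return(ifelse(is.infinite(x), paste0(ifelse(x > 0, ">", "<"), "limit"), x))
  }
  x
}

#' Write a JSON report with manifest and schema version
#'
#' Numbers are written at full precision; display rounding is a rendering
#' concern, never a storage one.
#'
#' @param report a (possibly nested) list of results.
#' @param path output file.
#' @param manifest a [run_manifest()].
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path, manifest = run_manifest("report")) {
  payload <- list(schema_version = "1.0", manifest = manifest,
                  report = strip_for_json(report))
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
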