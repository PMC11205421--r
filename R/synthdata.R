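# Seeded measurement simulator.
#
# Forward model for one LC-MS measurement of a dried-microsample extract:
#
#   c_vams    = (1-h) c_serum + h c_rbc   (+ residual endogenous blank level)
#   degraded  = c_vams * exp(-k * storage_days)
#   ratio     = slope * degraded * recovery * matrix_effect
#                 * exp(day_effect) * (1 + eps) + floor_noise
#
# with eps ~ N(0, intraday CV), day_effect a run-level log-scale shift shared
# by every measurement of the run (between-run variation), and floor_noise an
# additive response floor that makes the relative error blow up below the
# limit of quantification, as in real chromatographic data. The internal
# standard area is held at its nominal value, so the analyte area is
# ratio * istd_area.

peak_table_cols <- c("sample_id", "analyte", "role", "run_id", "day_index",
                     "analyte_area", "istd_area", "snr", "nominal_conc",
                     "hct", "storage_days", "storage_temp_c")

pt_rows <- function(sample_id, analyte, role, run_id, day_index,
                    analyte_area, istd_area, snr = NA_real_,
                    nominal_conc = NA_real_, hct = NA_real_,
                    storage_days = NA_real_, storage_temp_c = NA_real_) {
  tibble::tibble(sample_id = sample_id, analyte = analyte, role = role,
                 run_id = run_id, day_index = day_index,
                 analyte_area = analyte_area, istd_area = istd_area,
                 snr = snr, nominal_conc = nominal_conc, hct = hct,
                 storage_days = storage_days, storage_temp_c = storage_temp_c)
}

#' Measurement-noise model of the assay
#'
#' Per-analyte noise and attenuation parameters of the simulator, at the
#' magnitudes of the validated assay: intraday CV 2-8%, interday CV 3-12%
#' (read as the TOTAL pooled interday CV; the simulator derives the
#' between-run component as `sqrt(interday^2 - intraday^2)`), extraction
#' recovery 27-87%, matrix effects 85-95%. `snr_at_loq` anchors the simulated
#' signal-to-noise ratio (10 at the limit of quantification);
#' `noise_floor_cv_pct` is the additive response floor expressed as the CV it
#' induces at the LOQ.
#'
#' @param panel a `vams_panel` (defines the analyte set).
#' @return a tibble with columns `analyte`, `intraday_cv_pct`,
#'   `interday_cv_pct`, `recovery_pct`, `matrix_effect_pct`, `snr_at_loq`,
#'   `noise_floor_cv_pct`.
#' @export
default_noise_model <- function(panel = default_panel()) {
  defaults <- tibble::tribble(
    ~analyte, ~intraday_cv_pct, ~interday_cv_pct, ~recovery_pct, ~matrix_effect_pct,
    "A4",     5, 7,  81, 91,
    "F",      4, 7,  66, 85,
    "DHEA-S", 4, 10, 63, 95,
    "P4",     8, 12, 77, 88,
    "T",      2, 3,  84, 92,
    "T3",     3, 10, 31, 87,
    "T4",     5, 9,  27, 89,
    "E2",     3, 4,  87, 90
  )
  out <- defaults[match(names(panel), defaults$analyte), ]
  if (anyNA(out$analyte)) {
    missing <- names(panel)[is.na(out$analyte)]
    out$analyte[is.na(out$analyte)] <- missing
    out$intraday_cv_pct[is.na(out$intraday_cv_pct)] <- 5
    out$interday_cv_pct[is.na(out$interday_cv_pct)] <- 8
    out$recovery_pct[is.na(out$recovery_pct)] <- 80
    out$matrix_effect_pct[is.na(out$matrix_effect_pct)] <- 90
  }
  out$snr_at_loq <- 10
  out$noise_floor_cv_pct <- 15
  out
}

#' Noise-free variant of the noise model
#'
#' All random components zeroed; the deterministic attenuations (recovery,
#' matrix effect) are retained so that the forward model still exercises the
#' full calibration chain.
#'
#' @inheritParams default_noise_model
#' @return a noise-model tibble, see [default_noise_model()].
#' @export
zero_noise_model <- function(panel = default_panel()) {
  nm <- default_noise_model(panel)
  nm$intraday_cv_pct <- 0
  nm$interday_cv_pct <- 0
  nm$noise_floor_cv_pct <- 0
  nm
}

#' First-order storage degradation model
#'
#' One first-order rate per (analyte, storage temperature). Defaults: no
#' degradation frozen (-18 degC); at room temperature (20 degC) every analyte
#' retains at least 85% of its initial concentration through day 28
#' (`k = -log(0.90)/28`), except cortisol, which is parameterized to ~86%
#' retention at day 14 and below 85% at day 28 (`k = -log(0.86)/14`) — the
#' one analyte for which room-temperature storage is only supported for two
#' weeks.
#'
#' @inheritParams default_noise_model
#' @return a tibble with columns `analyte`, `temp_c`, `k_per_day`.
#' @export
default_degradation_model <- function(panel = default_panel()) {
  analytes <- names(panel)
  k20 <- ifelse(analytes == "F", -log(0.86) / 14, -log(0.90) / 28)
  tibble::tibble(
    analyte = rep(analytes, 2),
    temp_c = rep(c(20, -18), each = length(analytes)),
    k_per_day = c(k20, rep(0, length(analytes)))
  )
}

#' Between-subject hormone distribution model
#'
#' Lognormal between-subject serum concentrations per (analyte, sex), at the
#' magnitudes observed in healthy active adults, plus a truncated-normal
#' hematocrit distribution per sex (mean 0.40 female / 0.47 male, sd 0.02,
#' bounded to [0.30, 0.55]). Estradiol and progesterone carry female
#' parameters only.
#'
#' @return a list with `levels` (tibble `analyte`, `sex`, `mean`, `sd` in
#'   ng/mL) and `hct` (tibble `sex`, `mean`, `sd`, `lower`, `upper`).
#' @export
default_cohort_model <- function() {
  levels <- tibble::tribble(
    ~analyte, ~sex,     ~mean,  ~sd,
    "A4",     "male",   1.2,    0.5,
    "A4",     "female", 1.7,    0.7,
    "F",      "male",   136.3,  23.5,
    "F",      "female", 136.5,  39.5,
    "DHEA-S", "male",   1826.7, 843.8,
    "DHEA-S", "female", 1535.8, 728.4,
    "E2",     "female", 0.07,   0.07,
    "P4",     "female", 4.0,    4.7,
    "T",      "male",   5.2,    1.4,
    "T",      "female", 0.2,    0.1,
    "T3",     "male",   0.59,   0.2,
    "T3",     "female", 0.56,   0.1,
    "T4",     "male",   37.3,   12.6,
    "T4",     "female", 36.3,   7.6
  )
  hct <- tibble::tibble(sex = c("male", "female"), mean = c(0.47, 0.40),
                        sd = 0.02, lower = 0.30, upper = 0.55)
  list(levels = levels, hct = hct)
}

#' Instrument response model
#'
#' Per-analyte response slope (area ratio per ng/mL) and nominal internal
#' standard area. The default slope scales the upper calibration limit to an
#' area ratio of 2.
#'
#' @inheritParams default_noise_model
#' @return a tibble with columns `analyte`, `slope`, `istd_area`.
#' @export
response_model <- function(panel = default_panel()) {
  tibble::tibble(
    analyte = names(panel),
    slope = unname(vapply(panel, function(s) 2 / s$calibration_range[2],
                          numeric(1))),
    istd_area = 1e5
  )
}

model_row <- function(model, analyte) {
  i <- match(analyte, model$analyte)
  if (is.na(i)) stop("no model parameters for analyte ", analyte, call. = FALSE)
  as.list(model[i, ])
}

between_run_sd <- function(noise_row) {
  sqrt(max((noise_row$interday_cv_pct / 100)^2 -
             (noise_row$intraday_cv_pct / 100)^2, 0))
}

#' Simulate LC-MS measurements of one analyte
#'
#' Draws peak areas and SNR values from the forward measurement model (see
#' the file header of `synthdata.R`): compartment mixing at the sample
#' hematocrit, residual endogenous blank level, first-order storage
#' degradation, multiplicative intraday noise, a shared run-level (interday)
#' effect and an additive response floor. Uses the current RNG state; callers
#' control reproducibility by seeding.
#'
#' @param true_conc true concentration(s): serum-space (converted to
#'   whole-blood via the compartment model at `hct`) or already vams-space,
#'   per `space`.
#' @param spec the [analyte_spec()].
#' @param noise_row one row of a noise model (as a list or one-row tibble).
#' @param resp_row one row of a response model.
#' @param hct sample hematocrit.
#' @param space `"serum"` or `"vams"`.
#' @param day_effect log-scale run effect, typically drawn once per run as
#'   `rnorm(1, 0, sqrt(interday^2 - intraday^2)/100)`.
#' @param storage_days,k_per_day storage duration and first-order degradation
#'   rate.
#' @param include_blank_residual add the analyte's residual endogenous level
#'   (prepared surrogate-matrix samples carry it; default TRUE).
#' @return a tibble with columns `analyte_area`, `istd_area`, `snr`.
#' @export
simulate_measurement <- function(true_conc, spec, noise_row, resp_row,
                                 hct = 0.4, space = c("serum", "vams"),
                                 day_effect = 0, storage_days = 0,
                                 k_per_day = 0, include_blank_residual = TRUE) {
  space <- match.arg(space)
  stopifnot(inherits(spec, "analyte_spec"))
  n <- length(true_conc)
  c_vams <- if (space == "serum") vams_from_serum(true_conc, spec, hct) else true_conc
  if (include_blank_residual) c_vams <- c_vams + spec$blank_residual
  degraded <- c_vams * exp(-k_per_day * storage_days)
  atten <- (noise_row$recovery_pct / 100) * (noise_row$matrix_effect_pct / 100)
  mean_ratio <- resp_row$slope * degraded * atten
  eps <- stats::rnorm(n, 0, noise_row$intraday_cv_pct / 100)
  floor_sd <- resp_row$slope * spec$loq * atten * noise_row$noise_floor_cv_pct / 100
  floor_noise <- if (floor_sd > 0) stats::rnorm(n, 0, floor_sd) else 0
  ratio <- pmax(mean_ratio * exp(day_effect) * (1 + eps) + floor_noise, 0)
  ratio_at_loq <- resp_row$slope * spec$loq * atten * exp(day_effect)
  tibble::tibble(analyte_area = ratio * resp_row$istd_area,
                 istd_area = resp_row$istd_area,
                 snr = noise_row$snr_at_loq * ratio / ratio_at_loq)
}

#' Design of a validation batch
#'
#' Replicate structure of the validation experiments: 3 analytical runs with
#' a full calibration (6 levels + duplicate blanks) each; 6 QC replicates per
#' run for imprecision/accuracy; 5 LOQ levels (0.25x-4x the nominal LOQ) with
#' 6 replicates; 6+6 recovery sets; 4+4 matrix-effect sets; a carryover
#' triplet at the upper working range (50 ng/mL, 200 for DHEA-S); a
#' hematocrit series 0.30-0.70; and a storage grid (days 0-28 at 20 degC and
#' -18 degC, quadruplicates).
#'
#' @param n_runs,n_rep_qc runs and QC replicates per run.
#' @param n_cal_levels non-blank calibrator levels per run.
#' @param loq_rel_levels LOQ test levels relative to the nominal LOQ.
#' @param n_rep_loq replicates per LOQ level.
#' @param n_rep_recovery,n_rep_me replicates per recovery / matrix-effect set.
#' @param carry_conc,carry_conc_dheas carryover fortification, ng/mL.
#' @param carry_frac true injected carryover fraction of the simulator.
#' @param hct_grid,n_rep_hct hematocrit series and replicates per level.
#' @param storage_days,storage_temps,n_rep_storage stability grid.
#' @return a design list consumed by [simulate_validation_batch()].
#' @export
validation_design <- function(n_runs = 3, n_rep_qc = 6, n_cal_levels = 6,
                              loq_rel_levels = c(0.25, 0.5, 1, 2, 4),
                              n_rep_loq = 6, n_rep_recovery = 6, n_rep_me = 4,
                              carry_conc = 50, carry_conc_dheas = 200,
                              carry_frac = 5e-5,
                              hct_grid = seq(0.30, 0.70, by = 0.05),
                              n_rep_hct = 3,
                              storage_days = c(0, 1, 3, 5, 7, 14, 28),
                              storage_temps = c(20, -18), n_rep_storage = 4) {
  design <- list(n_runs = n_runs, n_rep_qc = n_rep_qc,
                 n_cal_levels = n_cal_levels, loq_rel_levels = loq_rel_levels,
                 n_rep_loq = n_rep_loq, n_rep_recovery = n_rep_recovery,
                 n_rep_me = n_rep_me, carry_conc = carry_conc,
                 carry_conc_dheas = carry_conc_dheas, carry_frac = carry_frac,
                 hct_grid = hct_grid, n_rep_hct = n_rep_hct,
                 storage_days = storage_days, storage_temps = storage_temps,
                 n_rep_storage = n_rep_storage)
  needed <- c("n_runs", "n_rep_qc", "n_cal_levels", "loq_rel_levels",
              "n_rep_loq", "n_rep_recovery", "n_rep_me", "storage_days")
  empty <- needed[vapply(design[needed], function(x) length(x) == 0, logical(1))]
  if (length(empty)) {
    stop("incomplete design: ", paste(empty, collapse = ", "), call. = FALSE)
  }
  if (!0 %in% storage_days) stop("storage_days must include day 0", call. = FALSE)
  design
}

qc_conc_for <- function(spec) {
  sqrt(spec$calibration_range[1] * spec$calibration_range[2])
}

cal_levels_for <- function(spec, n) {
  geom_seq(spec$calibration_range[1], spec$calibration_range[2], n)
}

#' Simulate a complete validation batch
#'
#' Generates one long-format peak table holding every measurement the
#' validation battery consumes, for every analyte of the panel. Sample roles
#' are encoded in `sample_id` prefixes: `CAL_` (calibrators), `BLK_` (run
#' blanks), `PREC_` (imprecision/accuracy QCs), `LOQ_` (LOQ level sets),
#' `REC_PRE_`/`REC_POST_` (recovery area sets), `ME_MAT_`/`ME_SOL_`
#' (matrix-effect area sets), `CARRY_` (carryover triplet), `HCT_`
#' (hematocrit series) and `STAB_` (storage series). The ground-truth
#' parameters are attached as attribute `"truth"` for parameter-recovery
#' testing.
#'
#' @param panel a `vams_panel`.
#' @param noise a noise model tibble ([default_noise_model()]).
#' @param deg a degradation model tibble ([default_degradation_model()]).
#' @param resp a response model tibble ([response_model()]).
#' @param design a [validation_design()].
#' @param seed integer RNG seed; identical seed and configuration give a
#'   byte-identical table.
#' @return a peak table (tibble) in the standard column layout.
#' @export
simulate_validation_batch <- function(panel = default_panel(),
                                      noise = default_noise_model(panel),
                                      deg = default_degradation_model(panel),
                                      resp = response_model(panel),
                                      design = validation_design(),
                                      seed = 1L) {
  stopifnot(inherits(panel, "vams_panel"))
  set.seed(seed)
  out <- list()
  for (code in names(panel)) {
    spec <- panel[[code]]
    nr <- model_row(noise, code)
    rr <- model_row(resp, code)
    qc <- qc_conc_for(spec)
    btw <- between_run_sd(nr)
    day_eff <- stats::rnorm(design$n_runs, 0, btw)
    atten <- (nr$recovery_pct / 100) * (nr$matrix_effect_pct / 100)

    for (r in seq_len(design$n_runs)) {
      run <- paste0("R", r)
      levels <- cal_levels_for(spec, design$n_cal_levels)
      m <- simulate_measurement(levels, spec, nr, rr, space = "vams",
                                day_effect = day_eff[r])
      out[[length(out) + 1L]] <- pt_rows(
        sprintf("CAL_L%d_%s", seq_along(levels), run), code, "calibrator", run,
        r, m$analyte_area, m$istd_area, m$snr, nominal_conc = levels, hct = 0.4)
      b <- simulate_measurement(c(0, 0), spec, nr, rr, space = "vams",
                                day_effect = day_eff[r])
      out[[length(out) + 1L]] <- pt_rows(
        sprintf("BLK_%d_%s", 1:2, run), code, "blank", run, r,
        b$analyte_area, b$istd_area, b$snr, hct = 0.4)
      q <- simulate_measurement(rep(qc, design$n_rep_qc), spec, nr, rr,
                                space = "vams", day_effect = day_eff[r])
      out[[length(out) + 1L]] <- pt_rows(
        sprintf("PREC_%d_%s", seq_len(design$n_rep_qc), run), code, "qc", run,
        r, q$analyte_area, q$istd_area, q$snr, nominal_conc = qc, hct = 0.4)
    }

    # LOQ level sets, analyzed within run 1
    for (i in seq_along(design$loq_rel_levels)) {
      lev <- design$loq_rel_levels[i] * spec$loq
      m <- simulate_measurement(rep(lev, design$n_rep_loq), spec, nr, rr,
                                space = "vams", day_effect = day_eff[1])
      out[[length(out) + 1L]] <- pt_rows(
        sprintf("LOQ_L%d_%d", i, seq_len(design$n_rep_loq)), code, "qc", "R1",
        1, m$analyte_area, m$istd_area, m$snr, nominal_conc = lev, hct = 0.4)
    }

    # Recovery / matrix effect / carryover: raw-area experiments
    rec_conc <- if (code == "DHEA-S") design$carry_conc_dheas else 20
    res <- spec$blank_residual
    pre <- rr$slope * (rec_conc + res) * atten *
      (1 + stats::rnorm(design$n_rep_recovery, 0, nr$intraday_cv_pct / 100))
    post <- rr$slope * (rec_conc + res * nr$recovery_pct / 100) *
      (nr$matrix_effect_pct / 100) *
      (1 + stats::rnorm(design$n_rep_recovery, 0, nr$intraday_cv_pct / 100))
    out[[length(out) + 1L]] <- pt_rows(
      c(sprintf("REC_PRE_%d", seq_len(design$n_rep_recovery)),
        sprintf("REC_POST_%d", seq_len(design$n_rep_recovery))),
      code, "qc", "R1", 1,
      c(pre, post) * rr$istd_area, rr$istd_area, nominal_conc = rec_conc)

    mat <- rr$slope * (rec_conc + res * nr$recovery_pct / 100) *
      (nr$matrix_effect_pct / 100) *
      (1 + stats::rnorm(design$n_rep_me, 0, nr$intraday_cv_pct / 100))
    sol <- rr$slope * rec_conc *
      (1 + stats::rnorm(design$n_rep_me, 0, nr$intraday_cv_pct / 100))
    out[[length(out) + 1L]] <- pt_rows(
      c(sprintf("ME_MAT_%d", seq_len(design$n_rep_me)),
        sprintf("ME_SOL_%d", seq_len(design$n_rep_me))),
      code, "qc", "R1", 1,
      c(mat, sol) * rr$istd_area, rr$istd_area, nominal_conc = rec_conc)

    carry_conc <- if (code == "DHEA-S") design$carry_conc_dheas else design$carry_conc
    high <- rr$slope * (carry_conc + res) * atten *
      (1 + stats::rnorm(1, 0, nr$intraday_cv_pct / 100)) * rr$istd_area
    out[[length(out) + 1L]] <- pt_rows(
      c("CARRY_HIGH", "CARRY_BLK1", "CARRY_BLK2"), code,
      c("qc", "blank", "blank"), "R1", 1,
      c(high, design$carry_frac * high, 0), rr$istd_area,
      nominal_conc = c(carry_conc, NA, NA))

    # Hematocrit series (serum-space truth fixed, hematocrit varied)
    qc_serum <- as.numeric(serum_from_vams(qc, spec, 0.4))
    for (h in design$hct_grid) {
      m <- simulate_measurement(rep(qc_serum, design$n_rep_hct), spec, nr, rr,
                                hct = h, space = "serum",
                                day_effect = day_eff[1])
      out[[length(out) + 1L]] <- pt_rows(
        sprintf("HCT_%02.0f_%d", 100 * h, seq_len(design$n_rep_hct)), code,
        "qc", "R1", 1, m$analyte_area, m$istd_area, m$snr,
        nominal_conc = qc_serum, hct = h)
    }

    # Storage stability series
    for (tc in design$storage_temps) {
      k <- deg$k_per_day[deg$analyte == code & deg$temp_c == tc]
      if (length(k) != 1L) {
        stop("degradation model lacks a rate for ", code, " at ", tc, " degC",
             call. = FALSE)
      }
      for (d in design$storage_days) {
        m <- simulate_measurement(rep(qc, design$n_rep_storage), spec, nr, rr,
                                  space = "vams", day_effect = day_eff[1],
                                  storage_days = d, k_per_day = k)
        out[[length(out) + 1L]] <- pt_rows(
          sprintf("STAB_%s_D%d_%d", ifelse(tc < 0, "F", "RT"), d,
                  seq_len(design$n_rep_storage)),
          code, "qc", "R1", 1, m$analyte_area, m$istd_area, m$snr,
          nominal_conc = qc, hct = 0.4, storage_days = d, storage_temp_c = tc)
      }
    }
  }
  tbl <- dplyr::bind_rows(out)
  attr(tbl, "truth") <- list(seed = seed, design = design, noise = noise,
                             deg = deg, resp = resp,
                             qc_conc = vapply(panel, qc_conc_for, numeric(1)))
  tbl
}

draw_cohort <- function(n_female, n_male, cohort) {
  n <- n_female + n_male
  sex <- c(rep("female", n_female), rep("male", n_male))
  hct <- numeric(n)
  for (s in unique(sex)) {
    hp <- cohort$hct[cohort$hct$sex == s, ]
    hct[sex == s] <- rtrunc_norm(sum(sex == s), hp$mean, hp$sd, hp$lower, hp$upper)
  }
  tibble::tibble(subject_id = sprintf("S%03d", seq_len(n)), sex = sex, hct = hct)
}

draw_true_serum <- function(subjects, analyte, cohort) {
  out <- rep(NA_real_, nrow(subjects))
  for (s in unique(subjects$sex)) {
    par <- cohort$levels[cohort$levels$analyte == analyte & cohort$levels$sex == s, ]
    if (nrow(par) == 1L) {
      lp <- lnorm_params(par$mean, par$sd)
      idx <- subjects$sex == s
      out[idx] <- stats::rlnorm(sum(idx), lp["meanlog"], lp["sdlog"])
    }
  }
  out
}

#' Simulate a paired serum-vs-capillary study
#'
#' Per subject, a true serum concentration is drawn from the cohort model and
#' measured twice: directly as serum (multiplicative error at the intraday
#' CV), and through the full capillary chain — compartment mixing at the
#' subject's hematocrit, forward measurement model, quantification against a
#' simulated in-run calibration, and compartment correction back to a serum
#' equivalent (at the subject's true hematocrit or at the assumed
#' standardization value 0.40).
#'
#' With `null = TRUE` the capillary chain is replaced by a second direct
#' measurement of the same truth with an independent error of the same
#' magnitude — both members of each pair then share one distribution, which
#' is the configuration for checking the calibration (type-I error) of the
#' paired tests.
#'
#' @param n_female,n_male subjects per sex (defaults 10 + 1).
#' @param cohort a [default_cohort_model()]-shaped list.
#' @param noise,resp noise and response models.
#' @param panel a `vams_panel`.
#' @param analytes analyte codes to simulate (default: the six analytes
#'   quantifiable in both sexes).
#' @param correction_hct `"true"` (subject's hematocrit) or `"assumed"`
#'   (standardization value).
#' @param assumed_hct the standardization hematocrit.
#' @param null simulate under the no-difference null (see above).
#' @param seed integer RNG seed.
#' @return a tibble with columns `subject_id`, `sex`, `analyte`, `hct`,
#'   `true_serum`, `c_serum`, `c_vams_corrected`.
#' @export
simulate_paired_study <- function(n_female = 10, n_male = 1,
                                  cohort = default_cohort_model(),
                                  noise = default_noise_model(panel),
                                  panel = default_panel(),
                                  resp = response_model(panel),
                                  analytes = c("A4", "F", "DHEA-S", "T", "T3", "T4"),
                                  correction_hct = c("true", "assumed"),
                                  assumed_hct = 0.4, null = FALSE, seed = 1L) {
  correction_hct <- match.arg(correction_hct)
  if (n_female + n_male < 3) stop("at least 3 subjects are required", call. = FALSE)
  set.seed(seed)
  subjects <- draw_cohort(n_female, n_male, cohort)
  out <- list()
  for (code in analytes) {
    spec <- panel[[code]]
    if (is.null(spec)) stop("analyte not in panel: ", code, call. = FALSE)
    nr <- model_row(noise, code)
    rr <- model_row(resp, code)
    truth <- draw_true_serum(subjects, code, cohort)
    keep <- !is.na(truth)
    tr <- truth[keep]
    n <- sum(keep)
    c_serum <- tr * (1 + stats::rnorm(n, 0, nr$intraday_cv_pct / 100))
    if (null) {
      corrected <- tr * (1 + stats::rnorm(n, 0, nr$intraday_cv_pct / 100))
    } else {
      day_eff <- stats::rnorm(1, 0, between_run_sd(nr))
      levels <- cal_levels_for(spec, 6)
      cal <- simulate_measurement(levels, spec, nr, rr, space = "vams",
                                  day_effect = day_eff)
      blk <- simulate_measurement(c(0, 0), spec, nr, rr, space = "vams",
                                  day_effect = day_eff)
      blank_ratio <- mean(area_ratio(blk$analyte_area, blk$istd_area))
      curve <- fit_calibration(levels, area_ratio(cal$analyte_area, cal$istd_area),
                               blank_ratio = blank_ratio, weighting = "1/x",
                               analyte = code)
      m <- simulate_measurement(tr, spec, nr, rr, hct = subjects$hct[keep],
                                space = "serum", day_effect = day_eff)
      q <- quantify(area_ratio(m$analyte_area, m$istd_area), curve, spec)
      h_corr <- if (correction_hct == "true") subjects$hct[keep] else assumed_hct
      corrected <- as.numeric(serum_from_vams(q$conc, spec, h_corr))
    }
    out[[length(out) + 1L]] <- tibble::tibble(
      subject_id = subjects$subject_id[keep], sex = subjects$sex[keep],
      analyte = code, hct = subjects$hct[keep], true_serum = tr,
      c_serum = c_serum, c_vams_corrected = corrected)
  }
  dplyr::bind_rows(out)
}

#' Simulate a field cohort of self-collected capillary samples
#'
#' Draws per-subject true serum concentrations and hematocrits from the
#' cohort model and emits a single-run peak table: one calibration set
#' (calibrators + duplicate blanks) per analyte plus one capillary sample
#' row per subject and analyte. Estradiol and progesterone are collected
#' from female subjects only. The ground truth is attached as attribute
#' `"truth"`.
#'
#' @param n_female,n_male subjects per sex.
#' @inheritParams simulate_paired_study
#' @return a peak table (tibble); `attr(x, "truth")` holds `subject_id`,
#'   `sex`, `analyte`, `hct`, `true_serum`.
#' @export
simulate_cohort <- function(n_female = 32, n_male = 18,
                            cohort = default_cohort_model(),
                            noise = default_noise_model(panel),
                            panel = default_panel(),
                            resp = response_model(panel), seed = 1L) {
  set.seed(seed)
  if (n_female + n_male == 0) {
    empty <- pt_rows(character(0), character(0), character(0), character(0),
                     integer(0), numeric(0), numeric(0))
    attr(empty, "truth") <- tibble::tibble(subject_id = character(0))
    return(empty)
  }
  subjects <- draw_cohort(n_female, n_male, cohort)
  out <- list()
  truth <- list()
  for (code in names(panel)) {
    spec <- panel[[code]]
    nr <- model_row(noise, code)
    rr <- model_row(resp, code)
    day_eff <- stats::rnorm(1, 0, between_run_sd(nr))
    levels <- cal_levels_for(spec, 6)
    cal <- simulate_measurement(levels, spec, nr, rr, space = "vams",
                                day_effect = day_eff)
    out[[length(out) + 1L]] <- pt_rows(
      sprintf("CAL_L%d_R1", seq_along(levels)), code, "calibrator", "R1", 1,
      cal$analyte_area, cal$istd_area, cal$snr, nominal_conc = levels, hct = 0.4)
    blk <- simulate_measurement(c(0, 0), spec, nr, rr, space = "vams",
                                day_effect = day_eff)
    out[[length(out) + 1L]] <- pt_rows(
      sprintf("BLK_%d_R1", 1:2), code, "blank", "R1", 1,
      blk$analyte_area, blk$istd_area, blk$snr, hct = 0.4)
    tr <- draw_true_serum(subjects, code, cohort)
    keep <- !is.na(tr)
    if (!any(keep)) next
    m <- simulate_measurement(tr[keep], spec, nr, rr, hct = subjects$hct[keep],
                              space = "serum", day_effect = day_eff,
                              include_blank_residual = FALSE)
    out[[length(out) + 1L]] <- pt_rows(
      subjects$subject_id[keep], code, "sample", "R1", 1,
      m$analyte_area, m$istd_area, m$snr, hct = subjects$hct[keep])
    truth[[length(truth) + 1L]] <- tibble::tibble(
      subject_id = subjects$subject_id[keep], sex = subjects$sex[keep],
      analyte = code, hct = subjects$hct[keep], true_serum = tr[keep])
  }
  tbl <- dplyr::bind_rows(out)
  attr(tbl, "truth") <- dplyr::bind_rows(truth)
  tbl
}
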