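# End-to-end study orchestration: load/simulate a cohort, calibrate (FH,
# LMP, joint), agreement reporting, association with and without
# calibration, bootstrap SEs, and the ultrasound-availability sensitivity
# analysis.

GA_RANGE <- c(0, 60)     # plausible gestational age, weeks
BW_RANGE <- c(200, 7000) # plausible birth weight, grams

#' Load a cohort from CSV
#'
#' Expects one header row with the cohort column names; missing values may
#' be encoded as empty fields or `NA`. Unknown columns are preserved but
#' ignored. Values are range-validated: GA in (0, 60) weeks, birth weight
#' in (200, 7000) grams, binary columns in {0, 1}.
#'
#' @param path CSV file path.
#' @return A cohort `data.frame`.
#' @export
load_cohort <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("cohort file not found: %s", path), call. = FALSE)
  }
  cohort <- tryCatch(
    utils::read.csv(path, na.strings = c("", "NA"),
                    stringsAsFactors = FALSE),
    error = function(e) stop(sprintf("cannot parse cohort CSV (empty or malformed): %s",
                                     conditionMessage(e)), call. = FALSE)
  )
  if (nrow(cohort) == 0L || ncol(cohort) < 2L) {
    stop("cohort file is empty or lacks a valid header", call. = FALSE)
  }
  validate_cohort(cohort)
  cohort
}

validate_cohort <- function(cohort) {
  problems <- character()
  check_range <- function(col, lo, hi) {
    if (!col %in% names(cohort)) return()
    v <- cohort[[col]]
    if (!is.numeric(v)) {
      problems <<- c(problems, sprintf("column '%s' is not numeric", col))
      return()
    }
    bad <- which(!is.na(v) & (v <= lo | v >= hi))
    if (length(bad) > 0L) {
      problems <<- c(problems, sprintf(
        "column '%s': %d value(s) outside (%g, %g), first at row %d (value %g)",
        col, length(bad), lo, hi, bad[1], v[bad[1]]))
    }
  }
  for (col in c("ga_us", "ga_fh", "ga_lmp", "T_true")) {
    check_range(col, GA_RANGE[1], GA_RANGE[2])
  }
  check_range("birth_weight", BW_RANGE[1], BW_RANGE[2])
  for (col in c("first_pregnancy", "malaria", "syphilis", "hiv", "baby_sex",
                "neonatal_death", "low_birth_weight")) {
    if (!col %in% names(cohort)) next
    v <- cohort[[col]]
    bad <- which(!is.na(v) & !(v %in% c(0, 1)))
    if (length(bad) > 0L) {
      problems <- c(problems, sprintf(
        "column '%s': %d non-binary value(s), first at row %d",
        col, length(bad), bad[1]))
    }
  }
  if (length(problems) > 0L) {
    stop(paste(c("cohort validation failed:", problems), collapse = "\n  "),
         call. = FALSE)
  }
  invisible(cohort)
}

#' Write a cohort to CSV
#'
#' One header row, cohort column names, missing values as empty fields.
#'
#' @param cohort cohort `data.frame`.
#' @param path output CSV path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

agreement_row <- function(method, status, ga, ga_us, k, preterm_cutoff) {
  ba <- bland_altman(ga, ga_us, k = k)
  data.frame(
    method = method, calibration_status = status,
    n_pairs = ba$n_pairs,
    mean_ga = mean(ga, na.rm = TRUE), sd_ga = stats::sd(ga, na.rm = TRUE),
    mean_diff = ba$mean_diff, sd_diff = ba$sd_diff,
    loa_low = ba$loa_low, loa_high = ba$loa_high,
    p_bias = ba$p_bias, pearson_rho = ba$pearson_rho,
    preterm_rate = preterm_rate(ga, preterm_cutoff)$rate,
    stringsAsFactors = FALSE
  )
}

association_row <- function(est, method) {
  data.frame(
    outcome = est$outcome, exposure_form = est$exposure_form,
    method = method, calibration_status = est$calibration_status,
    log_or = est$log_or, se = est$se, or_ = est$or_,
    ci_low = est$ci_low, ci_high = est$ci_high, n_used = est$n_used,
    naive_se = if (is.null(est$naive_se)) NA_real_ else est$naive_se,
    n_failed = if (is.null(est$n_failed)) NA_integer_ else est$n_failed,
    stringsAsFactors = FALSE
  )
}

measure_spec <- function(measure, z_variables, exclude_birth_weight) {
  q <- switch(measure, fh = "fh", lmp = "lmp", joint = c("fh", "lmp"),
              stop(sprintf("unknown measure '%s'", measure), call. = FALSE))
  predictor_spec(q, z_variables, exclude_birth_weight = exclude_birth_weight)
}

#' Run the full calibration study on a cohort
#'
#' Executes the complete analysis: gold-standard trimming, calibration in
#' FH-only, LMP-only and joint FH+LMP variants, agreement of raw and
#' calibrated GA against ultrasound (a Table-2-style analogue, including
#' preterm rates), and logistic association of GA with neonatal death and
#' low birth weight for each outcome x exposure form x measure x
#' calibration status (a Table-3-style analogue), with two-stage bootstrap
#' standard errors for the calibrated rows. The low-birth-weight analyses
#' exclude birth weight from the calibration predictors.
#'
#' @param cohort cohort `data.frame` (e.g. from [simulate_study_cohort()]
#'   or [load_cohort()]).
#' @param z_variables error-free covariates for the calibration stage.
#' @param boot a [bootstrap_spec()]; its seed is re-derived per analysis
#'   row from `seed` so rows use independent streams. `NULL` skips the
#'   bootstrap (calibrated rows then carry naive model-based SEs).
#' @param trim trim extreme ultrasound values when fitting calibrations.
#' @param preterm_cutoff weeks (preterm strictly below).
#' @param loa_k Bland-Altman limits-of-agreement multiplier.
#' @param measures calibration variants to run, subset of
#'   `c("fh", "lmp", "joint")`.
#' @param seed master seed for all bootstrap streams.
#' @return An object of class `study_report`: `agreement_table`,
#'   `association_table`, `calibration_models`, `provenance`.
#' @export
run_full_analysis <- function(cohort,
                              z_variables = default_z_variables(),
                              boot = bootstrap_spec(),
                              trim = TRUE, preterm_cutoff = 37,
                              loa_k = 2,
                              measures = c("fh", "lmp", "joint"),
                              seed = 1L) {
  validate_cohort(cohort)
  measures <- match.arg(measures, several.ok = TRUE)

  # Calibrations on the full covariate set (agreement + mortality analyses)
  models <- lapply(measures, function(m) {
    fit_calibration(cohort, measure_spec(m, z_variables, FALSE), trim = trim)
  })
  names(models) <- measures
  calibrated <- lapply(models, predict_calibrated, cohort = cohort)

  raw_rows <- lapply(intersect(c("fh", "lmp"), measures), function(m) {
    agreement_row(m, "uncalibrated", cohort[[paste0("ga_", m)]],
                  cohort$ga_us, loa_k, preterm_cutoff)
  })
  cal_rows <- lapply(measures, function(m) {
    agreement_row(m, "calibrated", calibrated[[m]], cohort$ga_us,
                  loa_k, preterm_cutoff)
  })
  agreement <- do.call(rbind, c(raw_rows, cal_rows))

  assoc <- list()
  stream <- 0L
  for (outcome in c("neonatal_death", "low_birth_weight")) {
    excl_bw <- outcome == "low_birth_weight"
    for (form in c("continuous", "preterm")) {
      # uncalibrated rows: raw FH / raw LMP
      for (m in intersect(c("fh", "lmp"), measures)) {
        ga_raw <- cohort[[paste0("ga_", m)]]
        expo <- if (form == "preterm") {
          as.integer(ga_raw < preterm_cutoff)
        } else {
          ga_raw
        }
        est <- fit_logistic_univariable(cohort[[outcome]], expo,
                                        outcome_name = outcome,
                                        exposure_form = form,
                                        calibration_status = "uncalibrated")
        assoc[[length(assoc) + 1L]] <- association_row(est, m)
      }
      # calibrated rows: FH, LMP, joint (two-stage bootstrap)
      for (m in measures) {
        stream <- stream + 1L
        spec_m <- measure_spec(m, z_variables, excl_bw)
        est <- if (is.null(boot)) {
          model <- fit_calibration(cohort, spec_m, trim = trim)
          ga_cal <- predict_calibrated(model, cohort)
          expo <- if (form == "preterm") {
            as.integer(ga_cal < preterm_cutoff)
          } else {
            ga_cal
          }
          fit_logistic_univariable(cohort[[outcome]], expo,
                                   outcome_name = outcome,
                                   exposure_form = form,
                                   calibration_status = "calibrated")
        } else {
          boot_m <- boot
          boot_m$seed <- derive_seed(seed, stream)
          bootstrap_association(cohort, spec_m, outcome = outcome,
                                exposure_form = form, boot = boot_m,
                                trim = trim,
                                preterm_cutoff = preterm_cutoff)
        }
        assoc[[length(assoc) + 1L]] <- association_row(est, m)
      }
    }
  }
  association <- do.call(rbind, assoc)

  structure(
    list(
      agreement_table = agreement,
      association_table = association,
      calibration_models = models,
      provenance = list(
        seed = seed,
        n_records = nrow(cohort),
        z_variables = z_variables,
        trim = trim,
        preterm_cutoff = preterm_cutoff,
        loa_k = loa_k,
        bootstrap = if (is.null(boot)) NULL else unclass(boot)[
          c("n_replicates", "sample_size", "with_replacement", "ci_method")],
        package_version = as.character(utils::packageVersion("gacalib")),
        n_us = sum(!is.na(cohort$ga_us)),
        n_fh = sum(!is.na(cohort$ga_fh)),
        n_lmp = sum(!is.na(cohort$ga_lmp))
      )
    ),
    class = "study_report"
  )
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("Study report: %d records (US %d, FH %d, LMP %d)\n",
              x$provenance$n_records, x$provenance$n_us, x$provenance$n_fh,
              x$provenance$n_lmp))
  cat("\nAgreement vs ultrasound:\n")
  print(x$agreement_table, digits = 3)
  cat("\nAssociation estimates:\n")
  print(x$association_table, digits = 3)
  invisible(x)
}

#' Ultrasound-availability sensitivity analysis
#'
#' Restricts the cohort to records with all three GA measurements, then for
#' each availability fraction masks ultrasound by an independent Bernoulli
#' indicator (drawn once per fraction) and reruns calibration, association
#' and bootstrap. Shows how a smaller validation sub-sample inflates the
#' calibrated standard errors.
#'
#' @param cohort cohort `data.frame`.
#' @param fractions ultrasound-availability fractions in (0, 1].
#' @param seed master seed (masking and bootstrap streams derive from it).
#' @param measures subset of `c("fh", "lmp", "joint")`.
#' @param outcome,exposure_form outcome model settings.
#' @param z_variables,boot,trim,preterm_cutoff as in [run_full_analysis()].
#' @param redraw_mask if `TRUE`, the ultrasound-availability mask is
#'   redrawn inside every bootstrap replicate, so the uncertainty of *which*
#'   records carry ultrasound propagates into the SE; if `FALSE` the mask
#'   is drawn once per fraction and held fixed across replicates.
#' @return `data.frame` with one row per fraction x measure: fraction,
#'   measure, n records, ultrasound count after masking, log OR, bootstrap
#'   SE, CI.
#' @export
sensitivity_ultrasound_availability <- function(cohort,
                                                fractions = c(0.25, 0.5, 1),
                                                seed = 1L,
                                                measures = c("fh", "lmp",
                                                             "joint"),
                                                outcome = "neonatal_death",
                                                exposure_form = "continuous",
                                                z_variables =
                                                  default_z_variables(),
                                                boot = bootstrap_spec(),
                                                trim = TRUE,
                                                preterm_cutoff = 37,
                                                redraw_mask = FALSE) {
  if (any(fractions <= 0 | fractions > 1)) {
    stop("fractions must lie in (0, 1]", call. = FALSE)
  }
  triple <- cohort[!is.na(cohort$ga_us) & !is.na(cohort$ga_fh) &
                     !is.na(cohort$ga_lmp), , drop = FALSE]
  if (nrow(triple) == 0L) {
    stop("no records with all three GA measurements", call. = FALSE)
  }
  excl_bw <- outcome == "low_birth_weight"
  rows <- list()
  for (i in seq_along(fractions)) {
    f <- fractions[i]
    masked <- if (f < 1) {
      apply_availability(triple, p_us = f, p_fh = 1, p_lmp = 1,
                         seed = derive_seed(seed, 100 + i))
    } else {
      triple
    }
    for (m in measures) {
      spec_m <- measure_spec(m, z_variables, excl_bw)
      est <- if (is.null(boot)) {
        model <- fit_calibration(masked, spec_m, trim = trim)
        ga_cal <- predict_calibrated(model, masked)
        expo <- if (exposure_form == "preterm") {
          as.integer(ga_cal < preterm_cutoff)
        } else {
          ga_cal
        }
        fit_logistic_univariable(masked[[outcome]], expo,
                                 outcome_name = outcome,
                                 exposure_form = exposure_form,
                                 calibration_status = "calibrated")
      } else if (isTRUE(redraw_mask) && f < 1) {
        boot_m <- boot
        boot_m$seed <- derive_seed(seed, 200 + 10 * i + match(m, measures))
        # point estimate from the fixed mask; SE from replicates that each
        # redraw the availability mask before the two-stage refit
        point <- local({
          model <- fit_calibration(masked, spec_m, trim = trim,
                                   drop_degenerate = TRUE)
          ga_cal <- predict_calibrated(model, masked)
          expo <- if (exposure_form == "preterm") {
            as.integer(ga_cal < preterm_cutoff)
          } else {
            ga_cal
          }
          fit_logistic_univariable(masked[[outcome]], expo,
                                   outcome_name = outcome,
                                   exposure_form = exposure_form,
                                   calibration_status = "calibrated")
        })
        res <- bootstrap_statistic(triple, function(d) {
          d$ga_us[stats::rbinom(nrow(d), 1L, f) == 0L] <- NA_real_
          model <- fit_calibration(d, spec_m, trim = trim,
                                   drop_degenerate = TRUE)
          ga_cal <- predict_calibrated(model, d)
          expo <- if (exposure_form == "preterm") {
            as.integer(ga_cal < preterm_cutoff)
          } else {
            ga_cal
          }
          fit_logistic_univariable(d[[outcome]], expo)$log_or
        }, boot_m)
        if (res$n_failed > 0.1 * boot_m$n_replicates) {
          stop(sprintf("bootstrap failed in %d of %d replicates (> 10%%)",
                       res$n_failed, boot_m$n_replicates), call. = FALSE)
        }
        point$se <- res$se
        ci <- if (boot_m$ci_method == "percentile") {
          exp(unname(stats::quantile(res$estimates, c(0.025, 0.975))))
        } else {
          exp(point$log_or + c(-1, 1) * stats::qnorm(0.975) * res$se)
        }
        point$ci_low <- ci[1]; point$ci_high <- ci[2]
        point
      } else {
        boot_m <- boot
        boot_m$seed <- derive_seed(seed, 200 + 10 * i + match(m, measures))
        bootstrap_association(masked, spec_m, outcome = outcome,
                              exposure_form = exposure_form, boot = boot_m,
                              trim = trim, preterm_cutoff = preterm_cutoff)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        fraction = f, measure = m, n_records = nrow(masked),
        n_us = sum(!is.na(masked$ga_us)),
        log_or = est$log_or, se = est$se,
        ci_low = est$ci_low, ci_high = est$ci_high,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Write a study report to disk
#'
#' One CSV per table (`agreement.csv`, `association.csv`, and
#' `sensitivity.csv` if supplied) plus `provenance.json`.
#'
#' @param report a [run_full_analysis()] result.
#' @param dir output directory (created if needed).
#' @param sensitivity optional [sensitivity_ultrasound_availability()]
#'   table.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir, sensitivity = NULL) {
  stopifnot(inherits(report, "study_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    agreement = file.path(dir, "agreement.csv"),
    association = file.path(dir, "association.csv"),
    provenance = file.path(dir, "provenance.json")
  )
  utils::write.csv(report$agreement_table, paths["agreement"],
                   row.names = FALSE)
  utils::write.csv(report$association_table, paths["association"],
                   row.names = FALSE)
  jsonlite::write_json(report$provenance, paths["provenance"],
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(sensitivity)) {
    paths <- c(paths, sensitivity = file.path(dir, "sensitivity.csv"))
    utils::write.csv(sensitivity, paths["sensitivity"], row.names = FALSE)
  }
  invisible(paths)
}
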