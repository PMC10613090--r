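# Regression calibration: fit E(T | Q, Z) on the ultrasound validation
# sub-cohort and predict calibrated GA for every record with complete
# predictors, with or without ultrasound.

#' Predictor specification for a calibration model
#'
#' @param q_measures non-empty subset of `c("fh", "lmp")`: the error-prone
#'   measurement(s) entering the calibration model.
#' @param z_variables character vector of error-free covariate names (may
#'   be empty). Must be cohort covariate columns.
#' @param exclude_birth_weight drop `birth_weight` from `z_variables`; used
#'   for the low-birth-weight outcome, whose definition involves birth
#'   weight itself.
#' @return An object of class `predictor_spec`.
#' @export
predictor_spec <- function(q_measures = "fh",
                           z_variables = character(),
                           exclude_birth_weight = FALSE) {
  q_measures <- tolower(q_measures)
  if (length(q_measures) == 0L || !all(q_measures %in% c("fh", "lmp"))) {
    stop_field("q_measures", "must be a non-empty subset of {fh, lmp}")
  }
  q_measures <- unique(q_measures)
  bad <- setdiff(z_variables, COVARIATE_NAMES)
  if (length(bad) > 0L) {
    stop_field("z_variables",
               paste("unknown covariate(s):", paste(bad, collapse = ", ")))
  }
  if (isTRUE(exclude_birth_weight)) {
    z_variables <- setdiff(z_variables, "birth_weight")
  }
  structure(
    list(q_measures = q_measures,
         z_variables = z_variables,
         exclude_birth_weight = isTRUE(exclude_birth_weight)),
    class = "predictor_spec"
  )
}

#' The study's full error-free predictor set
#'
#' Maternal age, HIV, MUAC, malaria, syphilis, first pregnancy, education,
#' trimester at enrolment, haemoglobin at enrolment and delivery, infant
#' sex, and (unless excluded) birth weight.
#'
#' @param exclude_birth_weight drop `birth_weight` (for the LBW analysis).
#' @return Character vector of covariate names.
#' @export
default_z_variables <- function(exclude_birth_weight = FALSE) {
  z <- COVARIATE_NAMES
  if (exclude_birth_weight) z <- setdiff(z, "birth_weight")
  z
}

#' Trim extreme gold-standard values by nearest-rank percentiles
#'
#' Drops values at or beyond the `lower_pct`-th / `upper_pct`-th
#' percentiles of the non-missing values, with percentiles computed by the
#' nearest-rank rule (rank `ceiling(p/100 * n)`, floored at 1) and
#' inclusive comparisons, i.e. a value equal to a threshold is dropped.
#'
#' @param values numeric vector (NAs allowed; never kept).
#' @param lower_pct,upper_pct percentile bounds, `0 <= lower < upper <= 100`.
#' @return List with `keep` (logical mask over `values`), `lower` and
#'   `upper` (the realized thresholds), and `n_dropped`.
#' @export
trim_extreme_reference <- function(values, lower_pct = 0.5,
                                   upper_pct = 99.5) {
  if (!is.numeric(lower_pct) || !is.numeric(upper_pct) ||
      lower_pct < 0 || upper_pct > 100 || lower_pct >= upper_pct) {
    stop("percentile bounds must satisfy 0 <= lower < upper <= 100",
         call. = FALSE)
  }
  obs <- values[!is.na(values)]
  if (length(unique(obs)) < 3L) {
    stop("need at least 3 distinct values to trim (thresholds degenerate)",
         call. = FALSE)
  }
  srt <- sort(obs)
  n <- length(srt)
  rank_of <- function(p) max(1L, ceiling(p / 100 * n))
  lower <- srt[rank_of(lower_pct)]
  upper <- srt[rank_of(upper_pct)]
  keep <- !is.na(values) & values > lower & values < upper
  list(keep = keep, lower = lower, upper = upper,
       n_dropped = sum(!is.na(values)) - sum(keep))
}

calibration_predictors <- function(spec) {
  c(paste0("ga_", spec$q_measures), spec$z_variables)
}

# Coerce character covariates to factors so model.matrix gets stable
# reference-first contrasts; levels from the canonical marginals when known.
as_model_frame <- function(cohort, predictors) {
  mf <- cohort[, predictors, drop = FALSE]
  canon <- default_covariate_marginals()
  for (nm in predictors) {
    if (is.character(mf[[nm]])) {
      lev <- canon[[nm]]$levels
      mf[[nm]] <- if (!is.null(lev) && all(stats::na.omit(mf[[nm]]) %in% lev)) {
        factor(mf[[nm]], levels = lev)
      } else {
        factor(mf[[nm]])
      }
    }
  }
  mf
}

#' Fit a regression calibration model
#'
#' Ordinary least squares of ultrasound GA (the unbiased gold standard) on
#' the error-prone measurement(s) and error-free covariates, over
#' complete-case records of the ultrasound validation sub-cohort. The
#' fitted conditional mean is the calibration function E(T | Q, Z).
#' Optionally, extreme ultrasound values are first excluded by percentile
#' trimming ([trim_extreme_reference()]); trimmed records are excluded from
#' fitting only and may still receive predictions.
#'
#' @param cohort cohort `data.frame` with `ga_us` and the spec's predictors.
#' @param spec a [predictor_spec()].
#' @param trim logical; trim extreme `ga_us` before fitting.
#' @param trim_pcts length-2 percentile bounds for trimming.
#' @param drop_degenerate drop predictor columns that are constant over the
#'   fit sample (their effect is unidentifiable and absorbed into the
#'   intercept) instead of rejecting the design. Used by bootstrap
#'   replicates, where rare binary covariates routinely resample to a
#'   constant; the default keeps the strict rejection.
#' @return An object of class `calibration_model`: `predictor_spec`,
#'   `intercept`, `coefficients` (named, excluding intercept),
#'   `residual_sd`, `n_fit`, `fit_rows` (row indices of the cohort used in
#'   fitting), `trim_window` (realized thresholds or NULL), plus the
#'   terms/levels needed for prediction.
#' @examples
#' coh <- generate_cohort(sim_config(n_records = 500, seed = 1))
#' fit <- fit_calibration(coh, predictor_spec("fh"), trim = FALSE)
#' fit$coefficients
#' @export
fit_calibration <- function(cohort, spec, trim = TRUE,
                            trim_pcts = c(0.5, 99.5),
                            drop_degenerate = FALSE) {
  stopifnot(inherits(spec, "predictor_spec"))
  predictors <- calibration_predictors(spec)
  missing_cols <- setdiff(c("ga_us", predictors), names(cohort))
  if (length(missing_cols) > 0L) {
    stop(sprintf("cohort lacks column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  trim_window <- NULL
  fit_rows <- stats::complete.cases(cohort[, c("ga_us", predictors),
                                           drop = FALSE])
  if (isTRUE(trim)) {
    tr <- trim_extreme_reference(cohort$ga_us, trim_pcts[1], trim_pcts[2])
    trim_window <- c(tr$lower, tr$upper)
    fit_rows <- fit_rows & tr$keep
  }
  dat <- cohort[fit_rows, , drop = FALSE]
  # drop factor levels absent from the fit sample so rare categories do not
  # produce all-zero indicator columns
  mf <- droplevels(as_model_frame(dat, predictors))
  form <- stats::as.formula(paste("~", paste(predictors, collapse = " + ")))
  terms_obj <- stats::terms(form, data = mf)
  X <- stats::model.matrix(terms_obj, data = mf)
  y <- dat$ga_us
  dropped <- character()
  if (isTRUE(drop_degenerate) && ncol(X) > 1L) {
    const <- vapply(seq_len(ncol(X))[-1L],
                    function(j) length(unique(X[, j])) == 1L, logical(1))
    if (any(const)) {
      dropped <- colnames(X)[-1L][const]
      X <- X[, !c(FALSE, const), drop = FALSE]
    }
  }
  p <- ncol(X)
  if (nrow(X) < p + 1L) {  # n >= (#predictors excl. intercept) + 2
    stop(sprintf(
      "insufficient complete cases for calibration: %d available, need >= %d",
      nrow(X), p + 1L), call. = FALSE)
  }
  qr_X <- qr(X)
  if (qr_X$rank < p) {
    dropped <- colnames(X)[qr_X$pivot[(qr_X$rank + 1L):p]]
    stop(sprintf("rank-deficient calibration design; collinear: %s",
                 paste(dropped, collapse = ", ")), call. = FALSE)
  }
  beta <- qr.coef(qr_X, y)
  resid <- y - drop(X %*% beta)
  residual_sd <- sqrt(sum(resid^2) / (nrow(X) - p))
  xlev <- lapply(mf[vapply(mf, is.factor, logical(1))], levels)
  structure(
    list(
      predictor_spec = spec,
      intercept = unname(beta[1L]),
      coefficients = beta[-1L],
      residual_sd = residual_sd,
      n_fit = nrow(X),
      fit_rows = which(fit_rows),
      dropped_columns = dropped,
      trim_window = trim_window,
      terms = terms_obj,
      xlevels = xlev,
      mean_response = mean(y)
    ),
    class = "calibration_model"
  )
}

#' @export
print.calibration_model <- function(x, ...) {
  q <- paste(toupper(x$predictor_spec$q_measures), collapse = "+")
  cat(sprintf("Regression calibration model E(T|Q,Z), Q = %s\n", q))
  cat(sprintf("  n_fit = %d, residual SD = %.3f weeks\n",
              x$n_fit, x$residual_sd))
  if (!is.null(x$trim_window)) {
    cat(sprintf("  gold-standard trim window: (%.2f, %.2f) weeks\n",
                x$trim_window[1], x$trim_window[2]))
  }
  cat(sprintf("  intercept = %.4f\n", x$intercept))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Predict calibrated gestational age
#'
#' Evaluates the fitted conditional mean for every record whose required
#' predictors are all present — with or without ultrasound. Records missing
#' any required predictor get `NA`.
#'
#' @param model a [fit_calibration()] result.
#' @param cohort cohort `data.frame` covering the model's predictors.
#' @return Numeric vector of calibrated GA (weeks), `NA` where incomplete.
#' @export
predict_calibrated <- function(model, cohort) {
  stopifnot(inherits(model, "calibration_model"))
  predictors <- calibration_predictors(model$predictor_spec)
  missing_cols <- setdiff(predictors, names(cohort))
  if (length(missing_cols) > 0L) {
    stop(sprintf("cohort lacks model predictor column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  ok <- stats::complete.cases(cohort[, predictors, drop = FALSE])
  out <- rep(NA_real_, nrow(cohort))
  mf_all <- as_model_frame(cohort, predictors)
  # categories unseen at fit time have no coefficient: predict NA
  for (nm in names(model$xlevels)) {
    ok <- ok & (is.na(mf_all[[nm]]) |
                  as.character(mf_all[[nm]]) %in% model$xlevels[[nm]])
  }
  if (!any(ok)) return(out)
  mf <- droplevels(mf_all[ok, , drop = FALSE])
  for (nm in names(model$xlevels)) {
    mf[[nm]] <- factor(as.character(mf[[nm]]), levels = model$xlevels[[nm]])
  }
  X <- stats::model.matrix(stats::delete.response(model$terms), data = mf,
                           xlev = model$xlevels)
  # columns dropped as degenerate at fit time contribute nothing
  X <- X[, names(model$coefficients), drop = FALSE]
  out[ok] <- model$intercept + drop(X %*% model$coefficients)
  out
}
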