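# Logistic association of GA with binary birth outcomes, effect
# conversions, and the two-stage bootstrap that propagates calibration
# uncertainty into the standard error of the log odds ratio.

#' Bootstrap specification
#'
#' The study's resampling scheme: simple random sampling with replacement
#' of `sample_size` records per replicate (an m-out-of-n bootstrap with
#' m = 1500 by default), the standard error taken as the SD of the
#' replicate log odds ratios.
#'
#' @param n_replicates number of bootstrap replicates (default 1000).
#' @param sample_size records drawn per replicate (default 1500).
#' @param with_replacement draw with replacement (default TRUE).
#' @param seed integer RNG seed.
#' @param ci_method `"percentile"` (default; matches the asymmetric
#'   calibrated intervals) or `"normal"` (log OR +/- 1.96 SE).
#' @return An object of class `bootstrap_spec`.
#' @export
bootstrap_spec <- function(n_replicates = 1000, sample_size = 1500,
                           with_replacement = TRUE, seed = 1L,
                           ci_method = c("percentile", "normal")) {
  ci_method <- match.arg(ci_method)
  if (!is.numeric(n_replicates) || n_replicates < 2) {
    stop_field("n_replicates", "must be >= 2")
  }
  if (!is.numeric(sample_size) || sample_size < 1) {
    stop_field("sample_size", "must be >= 1")
  }
  structure(
    list(n_replicates = as.integer(n_replicates),
         sample_size = as.integer(sample_size),
         with_replacement = isTRUE(with_replacement),
         seed = seed, ci_method = ci_method),
    class = "bootstrap_spec"
  )
}

new_association_estimate <- function(log_or, se, n_used,
                                     outcome = NA_character_,
                                     exposure_form = NA_character_,
                                     calibration_status = NA_character_,
                                     ci = NULL, ...) {
  if (is.null(ci)) {
    ci <- exp(log_or + c(-1, 1) * stats::qnorm(0.975) * se)
  }
  structure(
    c(list(outcome = outcome, exposure_form = exposure_form,
           calibration_status = calibration_status,
           log_or = log_or, se = se, or_ = exp(log_or),
           ci_low = ci[1], ci_high = ci[2], n_used = n_used),
      list(...)),
    class = "association_estimate"
  )
}

#' @export
print.association_estimate <- function(x, ...) {
  cat(sprintf(
    "%s ~ GA (%s, %s): log OR %.3f (SE %.3f), OR %.3f (95%% CI %.3f; %.3f), n = %d\n",
    x$outcome, x$exposure_form, x$calibration_status, x$log_or, x$se, x$or_,
    x$ci_low, x$ci_high, x$n_used))
  invisible(x)
}

#' Univariable logistic regression of a binary outcome on GA
#'
#' Maximum-likelihood fit of `logit P(outcome = 1) = a + b * exposure` over
#' complete cases; the standard error is the model-based
#' (observed-information) one, and the 95% CI is Wald on the OR scale.
#' Degenerate inputs — no events, no non-events, constant exposure, or
#' complete separation — are rejected rather than returning a huge
#' unstable coefficient.
#'
#' @param outcome 0/1 vector.
#' @param exposure numeric (GA in weeks) or 0/1 (preterm indicator) vector.
#' @param outcome_name,exposure_form,calibration_status metadata labels
#'   carried into the result.
#' @return An `association_estimate`.
#' @examples
#' set.seed(1)
#' ga <- rnorm(500, 38.7, 2)
#' y <- rbinom(500, 1, plogis(-3 - 0.2 * (ga - 38.7)))
#' fit_logistic_univariable(y, ga)
#' @export
fit_logistic_univariable <- function(outcome, exposure,
                                     outcome_name = "outcome",
                                     exposure_form = "continuous",
                                     calibration_status = "uncalibrated") {
  if (length(outcome) != length(exposure)) {
    stop("outcome and exposure must have equal length", call. = FALSE)
  }
  ok <- !is.na(outcome) & !is.na(exposure)
  y <- outcome[ok]; x <- exposure[ok]
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1", call. = FALSE)
  if (sum(y) == 0L || sum(y) == length(y)) {
    stop("degenerate outcome: need at least one event and one non-event",
         call. = FALSE)
  }
  if (stats::sd(x) == 0) {
    stop("degenerate exposure: zero variance over complete cases",
         call. = FALSE)
  }
  # univariable complete separation: event and non-event exposure ranges
  # disjoint (the MLE diverges; glm can stop silently on a flat likelihood)
  if (max(x[y == 1]) < min(x[y == 0]) || max(x[y == 0]) < min(x[y == 1])) {
    stop("complete separation in logistic fit: exposure perfectly splits events from non-events",
         call. = FALSE)
  }
  fit <- withCallingHandlers(
    stats::glm(y ~ x, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-12, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        stop("quasi-complete separation in logistic fit", call. = FALSE)
      }
      invokeRestart("muffleWarning")
    }
  )
  est <- summary(fit)$coefficients
  if (!fit$converged || abs(est["x", "Estimate"]) > 15 ||
      est["x", "Std. Error"] > 100) {
    stop("logistic fit did not converge (separation or degeneracy)",
         call. = FALSE)
  }
  # polish the IRLS solution with Newton steps so the MLE and its
  # observed-information SE are exact to machine precision
  X <- unname(cbind(1, x))
  beta <- unname(stats::coef(fit))
  H <- NULL
  for (iter in 1:25) {
    p <- stats::plogis(drop(X %*% beta))
    H <- crossprod(X * (p * (1 - p)), X)
    step <- solve(H, crossprod(X, y - p))
    beta <- beta + drop(step)
    if (max(abs(step)) < 1e-12) break
  }
  new_association_estimate(
    log_or = beta[2],
    se = sqrt(solve(H)[2, 2]),
    n_used = length(y),
    outcome = outcome_name,
    exposure_form = exposure_form,
    calibration_status = calibration_status
  )
}

#' Convert a log odds ratio to an odds ratio
#' @param log_or finite log odds ratio.
#' @return `exp(log_or)`.
#' @export
or_from_log_or <- function(log_or) {
  if (!is.numeric(log_or) || length(log_or) != 1L || !is.finite(log_or)) {
    stop("log_or must be a single finite number", call. = FALSE)
  }
  exp(log_or)
}

#' Percent change in the magnitude of a log odds ratio after calibration
#'
#' `100 * (|calibrated| - |uncalibrated|) / |uncalibrated|`; positive
#' values mean calibration strengthened the association.
#'
#' @param log_or_uncal,log_or_cal log odds ratios (uncalibrated nonzero).
#' @return Percent change.
#' @export
percent_change_log_or <- function(log_or_uncal, log_or_cal) {
  if (!is.numeric(log_or_uncal) || log_or_uncal == 0) {
    stop("uncalibrated log OR must be nonzero", call. = FALSE)
  }
  100 * (abs(log_or_cal) - abs(log_or_uncal)) / abs(log_or_uncal)
}

#' Odds-ratio reduction in percentage points
#'
#' `100 * (or_uncal - or_cal)`: how many points of odds ratio the
#' calibration removed (for protective effects, a further reduction).
#'
#' @param or_uncal,or_cal positive odds ratios.
#' @return Percentage-point difference.
#' @export
or_reduction_points <- function(or_uncal, or_cal) {
  if (!is.numeric(or_uncal) || !is.numeric(or_cal) ||
      or_uncal <= 0 || or_cal <= 0) {
    stop("odds ratios must be positive", call. = FALSE)
  }
  100 * (or_uncal - or_cal)
}

#' Generic m-out-of-n bootstrap of a statistic
#'
#' Resamples rows of `data` per `boot` and applies `statistic` to each
#' replicate; replicates where `statistic` errors are dropped and counted.
#'
#' @param data a data.frame.
#' @param statistic function(data) -> single number.
#' @param boot a [bootstrap_spec()].
#' @return List with `estimates` (successful replicate values), `n_failed`,
#'   `se` (SD of estimates).
#' @export
bootstrap_statistic <- function(data, statistic, boot = bootstrap_spec()) {
  stopifnot(inherits(boot, "bootstrap_spec"))
  n <- nrow(data)
  if (!boot$with_replacement && boot$sample_size > n) {
    stop("sample_size exceeds data size without replacement", call. = FALSE)
  }
  with_seed(boot$seed, {
    vals <- rep(NA_real_, boot$n_replicates)
    for (b in seq_len(boot$n_replicates)) {
      idx <- sample.int(n, boot$sample_size, replace = boot$with_replacement)
      vals[b] <- tryCatch(statistic(data[idx, , drop = FALSE]),
                          error = function(e) NA_real_)
    }
    ok <- vals[!is.na(vals)]
    list(estimates = ok,
         n_failed = boot$n_replicates - length(ok),
         se = stats::sd(ok))
  })
}

#' Two-stage bootstrap association estimate with calibrated GA
#'
#' Point estimate: fit the calibration model on the full cohort's
#' ultrasound sub-sample, predict calibrated GA for all records, and fit
#' the univariable outcome logistic regression. Uncertainty: in each
#' bootstrap replicate the *entire* two-stage pipeline — calibration fit,
#' prediction, outcome fit — is redone on the resampled records, so the
#' resulting SE (the SD of replicate log ORs) includes the uncertainty of
#' the calibration step that the naive model-based SE ignores. Replicates
#' that fail to fit (e.g. event-free resamples of a rare outcome) are
#' dropped and counted; more than 10% failures is an error.
#'
#' @param cohort cohort data.frame.
#' @param spec a [predictor_spec()] for the calibration stage.
#' @param outcome `"neonatal_death"` or `"low_birth_weight"`.
#' @param exposure_form `"continuous"` or `"preterm"` (dichotomized at
#'   `preterm_cutoff` before the outcome fit).
#' @param boot a [bootstrap_spec()].
#' @param trim trim extreme ultrasound values in each calibration fit.
#' @param preterm_cutoff weeks; preterm is GA strictly below this.
#' @return An `association_estimate` with bootstrap `se`, CI per
#'   `boot$ci_method`, plus `naive_se` (model-based SE of the plug-in
#'   fit), `n_replicates_ok` and `n_failed`.
#' @export
bootstrap_association <- function(cohort, spec,
                                  outcome = c("neonatal_death",
                                              "low_birth_weight"),
                                  exposure_form = c("continuous", "preterm"),
                                  boot = bootstrap_spec(),
                                  trim = TRUE, preterm_cutoff = 37) {
  outcome <- match.arg(outcome)
  exposure_form <- match.arg(exposure_form)
  stopifnot(inherits(boot, "bootstrap_spec"))

  fit_once <- function(dat) {
    model <- fit_calibration(dat, spec, trim = trim, drop_degenerate = TRUE)
    ga_cal <- predict_calibrated(model, dat)
    expo <- if (exposure_form == "preterm") {
      as.integer(ga_cal < preterm_cutoff)
    } else {
      ga_cal
    }
    fit_logistic_univariable(dat[[outcome]], expo,
                             outcome_name = outcome,
                             exposure_form = exposure_form,
                             calibration_status = "calibrated")
  }

  point <- fit_once(cohort)
  res <- bootstrap_statistic(cohort, function(d) fit_once(d)$log_or, boot)
  if (res$n_failed > 0.1 * boot$n_replicates) {
    stop(sprintf("bootstrap failed in %d of %d replicates (> 10%%)",
                 res$n_failed, boot$n_replicates), call. = FALSE)
  }
  ci <- if (boot$ci_method == "percentile") {
    exp(unname(stats::quantile(res$estimates, c(0.025, 0.975))))
  } else {
    exp(point$log_or + c(-1, 1) * stats::qnorm(0.975) * res$se)
  }
  new_association_estimate(
    log_or = point$log_or, se = res$se, n_used = point$n_used,
    outcome = outcome, exposure_form = exposure_form,
    calibration_status = "calibrated", ci = ci,
    naive_se = point$se,
    n_replicates_ok = length(res$estimates),
    n_failed = res$n_failed
  )
}
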