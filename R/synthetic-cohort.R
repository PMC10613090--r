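# Synthetic cohort generator: latent true GA plus classical, mutually
# independent measurement errors for the three assessment methods.

# Covariate columns of a cohort table, in canonical order.
COVARIATE_NAMES <- c(
  "maternal_age", "education", "first_pregnancy", "trimester_enrol",
  "malaria", "syphilis", "hiv", "hb_enrol", "hb_delivery", "muac",
  "baby_sex", "birth_weight"
)

COHORT_COLUMNS <- c(
  "record_id", "T_true", "ga_us", "ga_fh", "ga_lmp",
  COVARIATE_NAMES, "neonatal_death", "low_birth_weight"
)

draw_covariates <- function(n, marginals) {
  draw_one <- function(name) {
    m <- marginals[[name]]
    # exact [[ indexing: $p would partial-match $probs
    if (!is.null(m[["p"]])) {
      stats::rbinom(n, 1L, m[["p"]])
    } else if (!is.null(m[["levels"]])) {
      factor(sample(m[["levels"]], n, replace = TRUE, prob = m[["probs"]]),
             levels = m[["levels"]])
    } else {
      lo <- if (is.null(m[["min"]])) -Inf else m[["min"]]
      hi <- if (is.null(m[["max"]])) Inf else m[["max"]]
      rtruncnorm(n, m[["mean"]], m[["sd"]], lo, hi)
    }
  }
  out <- lapply(setdiff(COVARIATE_NAMES, "birth_weight"), draw_one)
  names(out) <- setdiff(COVARIATE_NAMES, "birth_weight")
  out
}

#' Generate a fully observed synthetic cohort
#'
#' Draws one row per mother-infant pair under the structural model the
#' downstream analysis assumes: a latent true gestational age T from a
#' truncated normal; three error-prone measurements `ga_us = T + e_US`,
#' `ga_fh = T + bias_FH + e_FH`, `ga_lmp = T + bias_LMP + e_LMP` with
#' mutually independent zero-mean normal errors independent of T (the
#' classical error model); birth weight linear in T with normal noise;
#' neonatal death from a logistic model in T; and low birth weight defined
#' deterministically as birth weight below the cutoff. Covariates other
#' than birth weight are drawn independently of T from their marginals.
#'
#' All three measurements are fully observed here; use
#' [apply_availability()] (or [simulate_study_cohort()]) to impose the
#' study's partial-availability pattern.
#'
#' @param config a [sim_config()].
#' @return A `data.frame` with columns `record_id`, `T_true`, `ga_us`,
#'   `ga_fh`, `ga_lmp`, the covariates, `neonatal_death` and
#'   `low_birth_weight`.
#' @examples
#' coh <- generate_cohort(sim_config(n_records = 100, seed = 7))
#' cor(coh$ga_fh, coh$ga_us)
#' @export
generate_cohort <- function(config) {
  config <- validate_sim_config(config)
  n <- as.integer(config$n_records)
  with_seed(config$seed, {
    T_true <- rtruncnorm(n, config$mu_T, config$sigma_T,
                         config$T_bounds[1], config$T_bounds[2])
    ga_us <- T_true + stats::rnorm(n, 0, config$sigma_US)
    ga_fh <- T_true + config$bias_FH + stats::rnorm(n, 0, config$sigma_FH)
    ga_lmp <- T_true + config$bias_LMP + stats::rnorm(n, 0, config$sigma_LMP)
    Z <- draw_covariates(n, config$covariate_marginals)
    birth_weight <- config$bw_intercept +
      config$bw_slope * (T_true - config$mu_T) +
      stats::rnorm(n, 0, config$bw_sigma)
    birth_weight <- pmax(birth_weight, 300)
    p_death <- stats::plogis(config$intercept_death +
                               config$lambda_T_death * (T_true - config$mu_T))
    neonatal_death <- stats::rbinom(n, 1L, p_death)
    out <- data.frame(
      record_id = seq_len(n),
      T_true = T_true,
      ga_us = ga_us,
      ga_fh = ga_fh,
      ga_lmp = ga_lmp,
      stringsAsFactors = FALSE
    )
    for (nm in names(Z)) out[[nm]] <- Z[[nm]]
    out$birth_weight <- birth_weight
    out$neonatal_death <- neonatal_death
    out$low_birth_weight <- as.integer(birth_weight < config$lbw_cutoff)
    out
  })
}

#' Impose per-method availability on a cohort
#'
#' Each GA measurement is independently retained with its method's
#' probability and set to missing otherwise (an independent Bernoulli
#' indicator per record per method, as in the study's ultrasound
#' sensitivity analysis). The latent `T_true` column, when present, is
#' never masked.
#'
#' @param cohort a cohort `data.frame` with `ga_us`, `ga_fh`, `ga_lmp`.
#' @param p_us,p_fh,p_lmp retention probabilities in `[0, 1]`.
#' @param seed integer RNG seed.
#' @return The cohort with masked measurements.
#' @export
apply_availability <- function(cohort, p_us, p_fh, p_lmp, seed = 1L) {
  check_prob(p_us, "p_us")
  check_prob(p_fh, "p_fh")
  check_prob(p_lmp, "p_lmp")
  n <- nrow(cohort)
  with_seed(seed, {
    cohort$ga_us[stats::rbinom(n, 1L, p_us) == 0L] <- NA_real_
    cohort$ga_fh[stats::rbinom(n, 1L, p_fh) == 0L] <- NA_real_
    cohort$ga_lmp[stats::rbinom(n, 1L, p_lmp) == 0L] <- NA_real_
    cohort
  })
}

#' Generate a synthetic cohort with the study's availability pattern
#'
#' Convenience wrapper: [generate_cohort()] followed by
#' [apply_availability()] with the config's availability probabilities,
#' using a seed derived deterministically from the config seed.
#'
#' @param config a [sim_config()].
#' @return A cohort `data.frame` with missing measurements.
#' @export
simulate_study_cohort <- function(config) {
  cohort <- generate_cohort(config)
  apply_availability(cohort, config$p_avail_US, config$p_avail_FH,
                     config$p_avail_LMP, seed = derive_seed(config$seed, 1))
}

#' Reliability ratio of a classically mismeasured covariate
#'
#' The factor `sigma_T^2 / (sigma_T^2 + sigma_delta^2)` by which classical
#' measurement error with SD `sigma_delta` attenuates a regression slope on
#' a true covariate with SD `sigma_T` toward zero.
#'
#' @param sigma_T SD of the true covariate (> 0).
#' @param sigma_delta SD of the measurement error (>= 0).
#' @return The attenuation fraction in `(0, 1]`.
#' @examples
#' theoretical_attenuation(2.15, 3.0) # ~0.339: severe attenuation
#' @export
theoretical_attenuation <- function(sigma_T, sigma_delta) {
  if (!is.numeric(sigma_T) || length(sigma_T) != 1L || is.na(sigma_T) ||
      sigma_T <= 0) {
    stop_field("sigma_T", "must be a single positive number")
  }
  check_nonneg(sigma_delta, "sigma_delta")
  sigma_T^2 / (sigma_T^2 + sigma_delta^2)
}
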