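#' Default covariate marginal distributions
#'
#' Marginal settings for the error-free covariates Z of a synthetic cohort.
#' Defaults are plausible for a rural western-Kenyan antenatal cohort:
#' maternal age ~ 25 (SD 5.5) years, mostly primary education, roughly a
#' quarter first pregnancies and first-trimester enrolments, malaria 16%,
#' HIV 19%, syphilis ~1%, haemoglobin ~11 g/dL at enrolment, MUAC ~27 cm,
#' and a slight excess of male infants.
#'
#' Each element is a list: continuous variables take `mean`, `sd` and
#' truncation bounds `min`/`max`; binary variables take `p` (probability of
#' 1); categorical variables take `levels` and `probs`.
#'
#' @return Named list of marginal settings, one per covariate.
#' @export
default_covariate_marginals <- function() {
  list(
    maternal_age  = list(mean = 25.4, sd = 5.5, min = 13, max = 50),
    education     = list(levels = c("none", "primary", "secondary", "tertiary"),
                         probs = c(0.0098, 0.5590, 0.3090, 0.1222)),
    first_pregnancy = list(p = 0.258),
    trimester_enrol = list(levels = c("first", "second", "third"),
                           probs = c(0.272, 0.723, 0.005)),
    malaria       = list(p = 0.160),
    syphilis      = list(p = 0.0087),
    hiv           = list(p = 0.187),
    hb_enrol      = list(mean = 11.3, sd = 1.7, min = 4, max = 20),
    hb_delivery   = list(mean = 10.2, sd = 2.3, min = 4, max = 20),
    muac          = list(mean = 27.3, sd = 3.0, min = 8, max = 45),
    baby_sex      = list(p = 0.512)
  )
}

#' Simulation configuration for a synthetic pregnancy cohort
#'
#' Bundles every parameter of the synthetic-cohort generator: the latent
#' true gestational age (GA) distribution, the classical measurement-error
#' model for the three GA assessment methods (ultrasound, fundal height,
#' last menstrual period), per-method availability, the birth-weight model
#' and the neonatal-mortality logistic model.
#'
#' The defaults describe the cohort regime the generator emulates: true GA
#' truncated-normal with mean 38.7 and SD 2.15 weeks on 30-44 weeks;
#' ultrasound the most precise method (error SD 0.8 wk), fundal height
#' intermediate (SD 1.2 wk, +0.25 wk bias), LMP least precise (SD 3 wk);
#' availability 42.8% / 91.7% / 98.9%; neonatal mortality ~1.1% with a
#' log odds ratio of -0.2 per week of GA.
#'
#' @param n_records number of mother-infant pairs.
#' @param mu_T,sigma_T mean and SD (weeks) of latent true GA.
#' @param T_bounds length-2 truncation interval (weeks) for true GA.
#' @param sigma_US,sigma_FH,sigma_LMP measurement-error SDs (weeks).
#' @param bias_FH,bias_LMP additive biases (weeks); ultrasound is unbiased.
#' @param p_avail_US,p_avail_FH,p_avail_LMP per-method availability
#'   probabilities.
#' @param lambda_T_death log odds ratio of neonatal death per week of GA.
#' @param intercept_death log odds of death at GA = `mu_T`.
#' @param bw_intercept,bw_slope,bw_sigma birth-weight model: grams at
#'   `mu_T`, grams per week of GA, and residual SD in grams.
#' @param lbw_cutoff low-birth-weight threshold in grams.
#' @param covariate_marginals marginal settings for Z, see
#'   [default_covariate_marginals()].
#' @param seed integer RNG seed.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @seealso [generate_cohort()], [apply_availability()]
#' @export
sim_config <- function(n_records = 2750,
                       mu_T = 38.7,
                       sigma_T = 2.15,
                       T_bounds = c(30, 44),
                       sigma_US = 0.8,
                       bias_FH = 0.25,
                       sigma_FH = 1.2,
                       bias_LMP = 0,
                       sigma_LMP = 3.0,
                       p_avail_US = 0.428,
                       p_avail_FH = 0.917,
                       p_avail_LMP = 0.989,
                       lambda_T_death = -0.2,
                       intercept_death = stats::qlogis(0.011),
                       bw_intercept = 3209,
                       bw_slope = 150,
                       bw_sigma = 450,
                       lbw_cutoff = 2500,
                       covariate_marginals = default_covariate_marginals(),
                       seed = 1L) {
  cfg <- list(
    n_records = n_records, mu_T = mu_T, sigma_T = sigma_T,
    T_bounds = T_bounds, sigma_US = sigma_US, bias_FH = bias_FH,
    sigma_FH = sigma_FH, bias_LMP = bias_LMP, sigma_LMP = sigma_LMP,
    p_avail_US = p_avail_US, p_avail_FH = p_avail_FH,
    p_avail_LMP = p_avail_LMP, lambda_T_death = lambda_T_death,
    intercept_death = intercept_death, bw_intercept = bw_intercept,
    bw_slope = bw_slope, bw_sigma = bw_sigma, lbw_cutoff = lbw_cutoff,
    covariate_marginals = covariate_marginals, seed = seed
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param config object to validate.
#' @export
validate_sim_config <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop("config must be a 'sim_config' object", call. = FALSE)
  }
  if (!is.numeric(config$n_records) || length(config$n_records) != 1L ||
      is.na(config$n_records) || config$n_records < 0 ||
      config$n_records != round(config$n_records)) {
    stop_field("n_records", "must be a single non-negative integer")
  }
  check_nonneg(config$sigma_T, "sigma_T")
  for (f in c("sigma_US", "sigma_FH", "sigma_LMP", "bw_sigma")) {
    check_nonneg(config[[f]], f)
  }
  for (f in c("p_avail_US", "p_avail_FH", "p_avail_LMP")) {
    check_prob(config[[f]], f)
  }
  if (!is.numeric(config$T_bounds) || length(config$T_bounds) != 2L ||
      anyNA(config$T_bounds) || config$T_bounds[1] >= config$T_bounds[2]) {
    stop_field("T_bounds", "must be (lower, upper) with lower < upper")
  }
  for (f in c("mu_T", "bias_FH", "bias_LMP", "lambda_T_death",
              "intercept_death", "bw_intercept", "bw_slope", "lbw_cutoff",
              "seed")) {
    if (!is.numeric(config[[f]]) || length(config[[f]]) != 1L ||
        is.na(config[[f]])) {
      stop_field(f, "must be a single non-missing number")
    }
  }
  cm <- config$covariate_marginals
  if (!is.list(cm) ||
      !all(names(default_covariate_marginals()) %in% names(cm))) {
    stop_field("covariate_marginals",
               "must contain settings for every covariate")
  }
  config
}

#' Read a simulation configuration from a JSON file
#'
#' Any top-level key that is not a `sim_config` field is an error, so typos
#' in configuration files fail loudly rather than silently using defaults.
#'
#' @param path path to a JSON file whose keys are `sim_config` arguments.
#' @return A validated `sim_config`.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  do.call(sim_config, raw)
}
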