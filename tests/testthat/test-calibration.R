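test_that("nearest-rank trimming matches the spec examples", {
  tr <- trim_extreme_reference(1:1000, 0.5, 99.5)
  expect_equal(tr$lower, 5)
  expect_equal(tr$upper, 995)
  expect_equal(sum(tr$keep), 989)
  expect_setequal((1:1000)[!tr$keep], c(1:5, 995:1000))

  tr2 <- trim_extreme_reference(c(10, 20, 30), 0, 100)
  expect_equal(which(tr2$keep), 2L)

  expect_error(trim_extreme_reference(c(1, 1, 2)), "distinct")
  expect_error(trim_extreme_reference(1:10, 99, 1), "percentile")
})

test_that("trimming agrees with the rank-enumeration oracle on random lists", {
  withr::with_seed(42, {
    for (i in 1:25) {
      n <- sample(10:1000, 1)
      values <- round(rnorm(n, 38, 3), sample(0:2, 1))
      if (length(unique(values)) < 3) next
      lp <- runif(1, 0, 10)
      up <- runif(1, 90, 100)
      got <- trim_extreme_reference(values, lp, up)
      expect_identical(got$keep, oracle_trim_keep(values, lp, up))
      # kept values lie strictly inside the realized thresholds
      expect_true(all(values[got$keep] > got$lower &
                        values[got$keep] < got$upper))
    }
  })
})

test_that("fit_calibration recovers exact small-sample fits", {
  # identity calibration
  coh <- data.frame(ga_us = c(35, 38, 41, 39), ga_fh = c(35, 38, 41, 39))
  fit <- fit_calibration(coh, predictor_spec("fh"), trim = FALSE)
  expect_equal(fit$intercept, 0, tolerance = 1e-10)
  expect_equal(unname(fit$coefficients["ga_fh"]), 1, tolerance = 1e-10)
  expect_equal(fit$residual_sd, 0, tolerance = 1e-10)

  # hand-solved normal equations: y = 2x exactly
  coh2 <- data.frame(ga_us = c(2, 4, 6), ga_fh = c(1, 2, 3))
  fit2 <- fit_calibration(coh2, predictor_spec("fh"), trim = FALSE)
  expect_equal(fit2$intercept, 0, tolerance = 1e-10)
  expect_equal(unname(fit2$coefficients["ga_fh"]), 2, tolerance = 1e-10)
  expect_equal(fit2$n_fit, 3L)
})

test_that("fit_calibration rejects degenerate designs informatively", {
  coh <- data.frame(ga_us = c(2, 4), ga_fh = c(1, 2))
  expect_error(fit_calibration(coh, predictor_spec("fh"), trim = FALSE),
               "insufficient complete cases")

  coh2 <- small_cohort()
  coh2$hb_delivery <- coh2$hb_enrol  # exact collinearity
  expect_error(
    fit_calibration(coh2, predictor_spec("fh", c("hb_enrol", "hb_delivery")),
                    trim = FALSE),
    "collinear.*hb_delivery")

  expect_error(fit_calibration(coh2[, c("ga_us", "ga_lmp")],
                               predictor_spec("fh"), trim = FALSE),
               "ga_fh")
})

test_that("OLS fit agrees with the normal-equations oracle on random designs", {
  withr::with_seed(7, {
    for (i in 1:20) {
      n <- sample(15:50, 1)
      p_z <- sample(0:4, 1)
      z_names <- sample(c("maternal_age", "muac", "hb_enrol", "hb_delivery"),
                        p_z)
      coh <- data.frame(ga_us = rnorm(n, 38, 2), ga_fh = rnorm(n, 38, 2),
                        ga_lmp = rnorm(n, 38, 3))
      for (z in z_names) coh[[z]] <- rnorm(n)
      q <- sample(list("fh", "lmp", c("fh", "lmp")), 1)[[1]]
      fit <- fit_calibration(coh, predictor_spec(q, z_names), trim = FALSE)
      predictors <- c(paste0("ga_", q), z_names)
      X <- cbind(1, as.matrix(coh[, predictors]))
      beta <- oracle_ols(X, coh$ga_us)
      got <- c(fit$intercept, unname(fit$coefficients[predictors]))
      expect_equal(got, unname(beta), tolerance = 1e-8)
    }
  })
})

test_that("classical-error slope attenuates by the reliability ratio", {
  coh <- big_cohort()
  fit <- fit_calibration(coh, predictor_spec("fh"), trim = FALSE)
  attn <- theoretical_attenuation(2.15, 1.2)
  expect_equal(unname(fit$coefficients["ga_fh"]), attn,
               tolerance = 0.02 / attn)
})

test_that("predict_calibrated applies the fitted linear function and complete-case rule", {
  coh <- data.frame(ga_us = c(36, 39, 42, 38.5), ga_fh = c(36.5, 39, 41, 38))
  fit <- fit_calibration(coh, predictor_spec("fh"), trim = FALSE)
  new <- data.frame(ga_fh = c(40, NA))
  pred <- predict_calibrated(fit, new)
  expect_equal(pred[1], fit$intercept + fit$coefficients[["ga_fh"]] * 40)
  expect_true(is.na(pred[2]))
  expect_error(predict_calibrated(fit, data.frame(ga_lmp = 40)), "ga_fh")
})

test_that("in-sample calibrated GA is mean-unbiased and shrunk", {
  coh <- study_cohort()
  for (q in list("fh", "lmp", c("fh", "lmp"))) {
    spec <- predictor_spec(q, default_z_variables())
    fit <- fit_calibration(coh, spec, trim = TRUE)
    cal <- predict_calibrated(fit, coh)
    # least-squares residuals sum to zero over the fitted records
    expect_equal(mean(cal[fit$fit_rows]), mean(coh$ga_us[fit$fit_rows]),
                 tolerance = 1e-10)
    # conditional-expectation shrinkage vs the raw measure used
    raw <- coh[[paste0("ga_", q[1])]]
    expect_lte(sd(cal, na.rm = TRUE), sd(raw, na.rm = TRUE))
  }
})

test_that("calibration improves validity monotonically with nested predictors", {
  coh <- study_cohort()
  triple <- coh[complete.cases(coh[, c("ga_us", "ga_fh", "ga_lmp")]), ]
  z <- default_z_variables()
  fits <- lapply(list(fh = "fh", lmp = "lmp", joint = c("fh", "lmp")),
                 function(q) fit_calibration(triple, predictor_spec(q, z),
                                             trim = FALSE))
  rows <- fits$joint$fit_rows
  us <- triple$ga_us[rows]
  rho <- vapply(fits, function(f) {
    cor(predict_calibrated(f, triple)[rows], us)
  }, numeric(1))
  expect_gte(rho["fh"], abs(cor(triple$ga_fh[rows], us)))
  expect_gte(rho["lmp"], abs(cor(triple$ga_lmp[rows], us)))
  expect_gte(rho["joint"], rho["fh"])
  expect_gte(rho["joint"], rho["lmp"])
})

test_that("regressing truth on calibrated GA recovers slope 1", {
  coh <- big_cohort()
  fit <- fit_calibration(coh, predictor_spec("fh", default_z_variables()),
                         trim = TRUE)
  cal <- predict_calibrated(fit, coh)
  lmfit <- lm(coh$T_true ~ cal)
  slope <- coef(lmfit)[2]
  se <- summary(lmfit)$coefficients[2, 2]
  expect_lt(abs(slope - 1), 4 * se + 0.01)
})

test_that("predictor_spec validates and applies the birth-weight exclusion", {
  expect_error(predictor_spec(character()), "q_measures")
  expect_error(predictor_spec("us"), "q_measures")
  expect_error(predictor_spec("fh", "not_a_covariate"), "not_a_covariate")
  spec <- predictor_spec("fh", default_z_variables(),
                         exclude_birth_weight = TRUE)
  expect_false("birth_weight" %in% spec$z_variables)
})
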