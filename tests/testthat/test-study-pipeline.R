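test_that("cohort CSV round-trips with empty-field missing values", {
  coh <- simulate_study_cohort(sim_config(n_records = 150, seed = 9))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, path)
  header <- readLines(path, n = 1)
  expect_true(grepl("record_id", header))
  expect_false(grepl("NA", readLines(path)[2]))
  back <- load_cohort(path)
  expect_equal(back$ga_us, coh$ga_us, tolerance = 1e-12)
  expect_equal(back$birth_weight, coh$birth_weight, tolerance = 1e-12)
  expect_equal(back$education, as.character(coh$education))
})

test_that("load_cohort validates schema and ranges", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(character(), path)
  expect_error(load_cohort(path), "empty|header")

  coh <- generate_cohort(sim_config(n_records = 20, seed = 2))
  coh$ga_us[3] <- 75
  write_cohort(coh, path)
  expect_error(load_cohort(path), "ga_us.*row 3")

  coh$ga_us[3] <- 38
  coh$neonatal_death[5] <- 2
  write_cohort(coh, path)
  expect_error(load_cohort(path), "neonatal_death")

  expect_error(load_cohort("no/such/file.csv"), "not found")
})

test_that("run_full_analysis produces the full table layout deterministically", {
  coh <- study_cohort()
  rep1 <- run_full_analysis(coh, boot = NULL, seed = 3)
  rep2 <- run_full_analysis(coh, boot = NULL, seed = 3)
  expect_identical(rep1$agreement_table, rep2$agreement_table)
  expect_identical(rep1$association_table, rep2$association_table)

  # 2 outcomes x 2 forms x (2 uncalibrated + 3 calibrated) rows
  expect_equal(nrow(rep1$association_table), 20L)
  expect_equal(nrow(rep1$agreement_table), 5L)
  expect_true(all(rep1$association_table$n_used > 0))

  at <- rep1$agreement_table
  cal <- at[at$calibration_status == "calibrated", ]
  raw <- at[at$calibration_status == "uncalibrated", ]
  # calibration removes the mean bias (to rounding, over all scored pairs)
  expect_true(all(abs(cal$mean_diff) < 0.02))
  # and shrinks variability relative to the raw measure
  expect_lt(cal$sd_ga[cal$method == "fh"], raw$sd_ga[raw$method == "fh"])
  expect_lt(cal$sd_ga[cal$method == "lmp"], raw$sd_ga[raw$method == "lmp"])
  # joint calibration agrees best with ultrasound
  expect_equal(which.max(cal$pearson_rho), which(cal$method == "joint"))
})

test_that("near-zero measurement error collapses calibrated and raw analyses", {
  cfg <- sim_config(n_records = 1500, sigma_US = 0, sigma_FH = 0,
                    sigma_LMP = 0, bias_FH = 0.25, bias_LMP = 0, seed = 13)
  coh <- generate_cohort(cfg)
  # raw FH differs from ultrasound by the constant bias: the zero-variance
  # Bland-Altman warning is the documented behaviour here
  rep <- suppressWarnings(
    run_full_analysis(coh, boot = NULL, measures = c("fh", "lmp"), seed = 1))
  at <- rep$agreement_table
  expect_equal(at$mean_diff[at$method == "fh" &
                              at$calibration_status == "uncalibrated"], 0.25)
  expect_equal(at$mean_diff[at$method == "lmp" &
                              at$calibration_status == "uncalibrated"], 0)

  tab <- rep$association_table
  cont <- tab[tab$exposure_form == "continuous" &
                tab$outcome == "neonatal_death" & tab$method == "lmp", ]
  expect_equal(cont$log_or[cont$calibration_status == "calibrated"],
               cont$log_or[cont$calibration_status == "uncalibrated"],
               tolerance = 1e-6)
})

test_that("write_report emits the table files and provenance", {
  coh <- small_cohort()
  rep <- run_full_analysis(coh, boot = NULL, measures = "fh", seed = 5)
  dir <- withr::local_tempdir()
  paths <- write_report(rep, dir)
  expect_true(all(file.exists(paths)))
  prov <- jsonlite::read_json(file.path(dir, "provenance.json"))
  expect_equal(prov$n_records, nrow(coh))
  back <- utils::read.csv(file.path(dir, "association.csv"))
  expect_equal(nrow(back), nrow(rep$association_table))
})

test_that("sensitivity analysis masks ultrasound as specified", {
  expect_error(
    sensitivity_ultrasound_availability(study_cohort(), fractions = c(0, 1)),
    "fractions")

  coh <- generate_cohort(sim_config(n_records = 10000, seed = 19))
  sens <- sensitivity_ultrasound_availability(
    coh, fractions = c(0.25, 1), seed = 8, measures = "fh", boot = NULL,
    z_variables = c("maternal_age", "muac", "birth_weight"))
  expect_equal(nrow(sens), 2L)
  # binomial oracle for the masked ultrasound count
  expect_lt(abs(sens$n_us[sens$fraction == 0.25] - 2500),
            3 * sqrt(10000 * 0.25 * 0.75))
  expect_equal(sens$n_us[sens$fraction == 1], 10000)

  # fraction 1 reproduces the unmasked triple-complete analysis
  spec <- predictor_spec("fh", c("maternal_age", "muac", "birth_weight"))
  fit <- fit_calibration(coh, spec, trim = TRUE)
  est <- fit_logistic_univariable(coh$neonatal_death,
                                  predict_calibrated(fit, coh))
  expect_equal(sens$log_or[sens$fraction == 1], est$log_or,
               tolerance = 1e-10)
})

test_that("CLI simulate/calibrate/run wire the stages together", {
  dir <- withr::local_tempdir()
  cfg_path <- file.path(dir, "config.json")
  jsonlite::write_json(list(n_records = 400, seed = 6), cfg_path,
                       auto_unbox = TRUE)
  cohort_path <- file.path(dir, "cohort.csv")
  expect_message(
    gacalib_cli(c("simulate", "--config", cfg_path, "--out", cohort_path)),
    "400 records")

  cal_path <- file.path(dir, "calibrated.csv")
  expect_message(
    gacalib_cli(c("calibrate", "--cohort", cohort_path, "--measure", "fh",
                  "--out", cal_path)),
    "calibrated")
  out <- load_cohort(cal_path)
  expect_true("ga_calibrated" %in% names(out))
  expect_true(file.exists(paste0(cal_path, ".model.json")))

  agree_path <- file.path(dir, "agree.csv")
  gacalib_cli(c("agree", "--cohort", cal_path, "--method", "ga_calibrated",
                "--out", agree_path))
  row <- utils::read.csv(agree_path)
  expect_equal(row$n_pairs, sum(!is.na(out$ga_calibrated) &
                                  !is.na(out$ga_us)))

  expect_error(gacalib_cli(c("simulate")), "--out")
  expect_error(gacalib_cli(c("frobnicate", "--out", "x")), "unknown subcommand")
})
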