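test_that("zero-perturbation experiment yields perfect repeatability", {
  cfg <- experiment_config(population = population_config(
    n_patients = 8, bad_bolus_rate = 0),
    perturbation = zero_perturbation(), seed = 5)
  res <- run_repeatability_experiment(cfg)
  expect_true(all(res$report$agreement$r_spearman == 1))
  expect_true(all(res$report$agreement$mean_diff == 0))
  expect_true(all(res$report$agreement$sd_diff == 0))
})

test_that("experiment is deterministic under the master seed", {
  cfg <- experiment_config(population = population_config(n_patients = 5),
                           seed = 17)
  r1 <- run_repeatability_experiment(cfg)
  r2 <- run_repeatability_experiment(cfg)
  expect_identical(r1$measurements, r2$measurements)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  render_report(r1, d1); render_report(r2, d2)
  expect_identical(readLines(file.path(d1, "report.md")),
                   readLines(file.path(d2, "report.md")))
})

test_that("QC exclusions reconcile with bolus failures and are reported", {
  cfg <- experiment_config(population = population_config(
    n_patients = 30, bad_bolus_rate = 0.3), seed = 23)
  res <- run_repeatability_experiment(cfg)
  expect_gt(nrow(res$excluded), 0)
  analysed <- length(unique(res$measurements$patient_id))
  expect_equal(analysed + nrow(res$excluded), 30)
  d <- withr::local_tempdir()
  render_report(res, d)
  md <- readLines(file.path(d, "report.md"))
  expect_true(any(grepl(sprintf("excluded by bolus QC: %d", nrow(res$excluded)),
                        md)))
})

test_that("inflating perturbations never improves inter-operator correlation", {
  r_at_scale <- function(c) {
    pc0 <- perturbation_config()
    pc <- perturbation_config(
      valve_plane_sd = c * pc0$valve_plane_sd,
      axis_sd = c * pc0$axis_sd,
      motion_sd = c * pc0$motion_sd,
      inferior_contamination_sd = c * pc0$inferior_contamination_sd)
    cfg <- experiment_config(population = population_config(n_patients = 40),
                             perturbation = pc, seed = 29)
    res <- run_repeatability_experiment(cfg)
    ag <- subset(res$report$agreement,
                 comparison == "inter" & parameter == "mfr")
    ag$r_spearman[order(ag$model, ag$region)]
  }
  r1 <- r_at_scale(1); r2 <- r_at_scale(2); r4 <- r_at_scale(4)
  expect_true(all(r2 <= r1 + 0.02))
  expect_true(all(r4 <= r2 + 0.02))
})

test_that("all-excluded cohort raises an informative error", {
  cfg <- experiment_config(population = population_config(
    n_patients = 3, bad_bolus_rate = 1), seed = 31)
  expect_error(run_repeatability_experiment(cfg), "excluded by bolus QC")
})
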