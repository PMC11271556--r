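#' Configuration of the in-silico repeatability experiment
#'
#' Bundles every stage of the experiment: cohort generation, the simulated
#' operators' perturbation model, both kinetic models' settings, and the
#' master seed. Two operators are simulated; the first operator processes
#' every study twice (the second processing being an intra-operator
#' replicate), the second once.
#'
#' @param population A [population_config()].
#' @param perturbation A [perturbation_config()].
#' @param retention A [retention_config()].
#' @param extraction An [extraction_model()] used to convert uptake to MBF.
#' @param scheme Segment scheme.
#' @param min_rest_mbf Rest-MBF floor below which a segment is excluded from
#'   MFR aggregation.
#' @param dt_s Fine-grid step for compartment fitting (seconds).
#' @param seed Master seed; every random draw in the experiment derives from
#'   it (no wall-clock seeding).
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(population = population_config(),
                              perturbation = perturbation_config(),
                              retention = retention_config(),
                              extraction = extraction_model(),
                              scheme = aha17_scheme(),
                              min_rest_mbf = 0.05, dt_s = 0.5, seed = 1L) {
  stopifnot(inherits(population, "population_config"),
            inherits(perturbation, "perturbation_config"),
            inherits(retention, "retention_config"),
            inherits(extraction, "extraction_model"))
  validate_scheme(scheme)
  assert_scalar_num(seed, "seed")
  structure(list(population = population, perturbation = perturbation,
                 retention = retention, extraction = extraction,
                 scheme = scheme, min_rest_mbf = min_rest_mbf,
                 dt_s = dt_s, seed = as.integer(seed)),
            class = "experiment_config")
}

# Region-level values of one study pair under one model, as long rows.
quantify_pair <- function(pair, model, cfg) {
  fl_s <- compute_flow(pair$stress, model, cfg$extraction, cfg$retention,
                       cfg$scheme, cfg$dt_s)
  fl_r <- compute_flow(pair$rest, model, cfg$extraction, cfg$retention,
                       cfg$scheme, cfg$dt_s)
  mfr <- compute_mfr(fl_s, fl_r, cfg$scheme, cfg$min_rest_mbf)
  dplyr::bind_rows(
    dplyr::transmute(fl_s$territories, parameter = "stress_mbf",
                     region = .data$region, value = .data$mbf),
    dplyr::transmute(fl_r$territories, parameter = "rest_mbf",
                     region = .data$region, value = .data$mbf),
    dplyr::transmute(mfr$territories, parameter = "mfr",
                     region = .data$region, value = .data$mfr)) |>
    dplyr::mutate(model = .env$model,
                  n_nonconverged = if (.env$model == "1cm")
                    sum(!fl_s$fit$estimates$converged) +
                    sum(!fl_r$fit$estimates$converged) else 0L)
}

#' Run the full in-silico processing-repeatability experiment
#'
#' Simulates the cohort, excludes patients whose rest or stress bolus fails
#' [bolus_qc()], produces three processings per remaining patient (operator
#' 1 twice, operator 2 once) via seeded perturbations, quantifies every
#' processing with both kinetic models, and assembles the inter-operator
#' (operator 1 first processing vs operator 2) and intra-operator (operator
#' 1's two processings) repeatability report. Fully deterministic under the
#' master seed.
#'
#' @param cfg An [experiment_config()].
#' @param progress Print a progress line every 25 patients.
#' @return Object of class `experiment_result`: `measurements` (long tibble),
#'   `report` ([build_report()] output over both comparisons), `means`
#'   (first-operator mean +/- SD per model/parameter/region), `excluded`,
#'   `truth`, counts and the config.
#' @export
run_repeatability_experiment <- function(cfg, progress = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  pop <- cfg$population
  ids <- sprintf("pat%03d", seq_len(pop$n_patients))
  measurements <- vector("list", length(ids))
  excluded <- list()
  truths <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    pid <- ids[i]
    pair <- simulate_patient(pop, patient_id = pid,
                             seed = derive_seed(cfg$seed, "patient", pid),
                             scheme = cfg$scheme)
    qc_r <- bolus_qc(pair$rest$tacs$blood)
    qc_s <- bolus_qc(pair$stress$tacs$blood)
    if (!qc_r$pass || !qc_s$pass) {
      excluded[[pid]] <- tibble::tibble(
        patient_id = pid,
        reason = paste(stats::na.omit(c(qc_r$reason, qc_s$reason)),
                       collapse = "; "))
      next
    }
    truths[[i]] <- dplyr::mutate(truth_of(pair), patient_id = pid)
    procs <- list(
      op1_rep1 = list(seed = derive_seed(cfg$seed, pid, "op1"), rep = 1),
      op1_rep2 = list(seed = derive_seed(cfg$seed, pid, "op1"), rep = 2),
      op2      = list(seed = derive_seed(cfg$seed, pid, "op2"), rep = 1))
    rows <- purrr::imap(procs, function(pr, label) {
      ppair <- apply_operator_perturbation(pair, cfg$perturbation,
                                           operator_seed = pr$seed,
                                           replicate = pr$rep)
      dplyr::bind_rows(quantify_pair(ppair, "ret", cfg),
                       quantify_pair(ppair, "1cm", cfg)) |>
        dplyr::mutate(processing = label, patient_id = pid)
    })
    measurements[[i]] <- dplyr::bind_rows(rows)
    if (progress && i %% 25 == 0)
      message(sprintf("[experiment] %d/%d patients processed", i, length(ids)))
  }
  measurements <- dplyr::bind_rows(measurements)
  excluded <- if (length(excluded)) dplyr::bind_rows(excluded)
  else tibble::tibble(patient_id = character(0), reason = character(0))
  if (nrow(measurements) == 0)
    abort_input("all %d simulated patients were excluded by bolus QC",
                pop$n_patients)
  report <- build_report(measurements)
  means <- measurements |>
    dplyr::filter(.data$processing == "op1_rep1") |>
    dplyr::group_by(.data$model, .data$parameter, .data$region) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     n = dplyr::n(), .groups = "drop")
  structure(list(measurements = measurements, report = report, means = means,
                 excluded = excluded,
                 truth = dplyr::bind_rows(truths),
                 n_simulated = pop$n_patients, seed = cfg$seed, config = cfg),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> %d simulated, %d excluded, seed %d\n",
              x$n_simulated, nrow(x$excluded), x$seed))
  inter <- dplyr::filter(x$report$agreement, .data$comparison == "inter",
                         .data$parameter == "mfr")
  print(dplyr::select(inter, "model", "region", "r_spearman", "mean_diff",
                      "sd_diff"))
  invisible(x)
}
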