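#' Population configuration for the synthetic study generator
#'
#' Defines the cohort the generator emulates: a rest/dipyridamole-stress
#' dynamic SPECT population with rest MBF around 1 ml/min/g, flow reserve
#' around 1.8-1.9, and a 44% prevalence of inferior/inferolateral
#' post-infarction scar. All distributions are log-normal unless noted.
#'
#' @param n_patients Cohort size.
#' @param rest_mbf_median,rest_mbf_sdlog Median (ml/min/g) and log-SD of rest
#'   total MBF across patients.
#' @param mfr_median,mfr_sdlog Median and log-SD of the stress/rest flow
#'   ratio.
#' @param segment_sdlog Log-SD of per-segment flow heterogeneity within a
#'   patient (shared between rest and stress).
#' @param scar_prevalence Fraction of patients with a perfusion-defect scar.
#' @param scar_severity Fractional flow reduction inside scar segments.
#' @param scar_segments AHA segment numbers forming the scar block; default
#'   the inferior wall (basal/mid/apical inferior).
#' @param k2_range Range (1/min) of the washout rate; sestamibi is largely
#'   trapped, so washout is slow.
#' @param f_v_basal,f_v_mid,f_v_apical Mean blood spillover fraction per
#'   ring (basal segments sit nearest the cavity and valve plane).
#' @param f_v_sd SD of per-segment spillover jitter.
#' @param noise_scale Measurement noise scale: frame noise SD is
#'   `noise_scale * sqrt(value / duration_s)`, a Gaussian surrogate for
#'   Poisson counting noise after frame averaging.
#' @param bad_bolus_rate Fraction of patients with a dispersed/leaked bolus
#'   (late, flat first pass) that should fail [bolus_qc()].
#' @param peak_time_mean,peak_time_sd Bolus peak-time distribution (s).
#' @param alpha_shape Gamma-variate shape of the first pass.
#' @param tail_fraction_median,tail_fraction_sdlog Recirculation-tail
#'   amplitude distribution.
#' @param background_level Constant pre-injection background (fraction of
#'   bolus peak).
#' @param extracardiac_amplitude_median,extracardiac_amplitude_sdlog
#'   Hepatic/intestinal curve plateau distribution (relative to bolus peak).
#' @param extraction [extraction_model()] converting flow to uptake when
#'   building ground-truth K1.
#' @param dt_s Fine-grid step (s) for forward simulation.
#' @param seed Default master seed used by [simulate_population()].
#' @return An object of class `population_config`.
#' @export
population_config <- function(n_patients = 200,
                              rest_mbf_median = 1.0, rest_mbf_sdlog = 0.30,
                              mfr_median = 1.85, mfr_sdlog = 0.25,
                              segment_sdlog = 0.08,
                              scar_prevalence = 0.44, scar_severity = 0.5,
                              scar_segments = c(4, 10, 15),
                              k2_range = c(0.02, 0.12),
                              f_v_basal = 0.30, f_v_mid = 0.20,
                              f_v_apical = 0.15, f_v_sd = 0.03,
                              noise_scale = 0.05,
                              bad_bolus_rate = 0.08,
                              peak_time_mean = 25, peak_time_sd = 4,
                              alpha_shape = 3,
                              tail_fraction_median = 0.08,
                              tail_fraction_sdlog = 0.3,
                              background_level = 0.067,
                              extracardiac_amplitude_median = 0.8,
                              extracardiac_amplitude_sdlog = 0.3,
                              extraction = extraction_model(),
                              dt_s = 0.5, seed = 1L) {
  assert_scalar_num(scar_prevalence, "scar_prevalence", 0, 1)
  assert_scalar_num(scar_severity, "scar_severity", 0, 1)
  assert_scalar_num(rest_mbf_sdlog, "rest_mbf_sdlog", lo = 0)
  assert_scalar_num(mfr_sdlog, "mfr_sdlog", lo = 0)
  assert_scalar_num(noise_scale, "noise_scale", lo = 0)
  assert_scalar_num(bad_bolus_rate, "bad_bolus_rate", 0, 1)
  stopifnot(inherits(extraction, "extraction_model"))
  cfg <- as.list(environment())
  structure(cfg, class = "population_config")
}

# Per-ring mean spillover fraction for the 17 segments.
fv_base_by_segment <- function(pop) {
  ring <- aha17_scheme()$ring
  base <- c(basal = pop$f_v_basal, mid = pop$f_v_mid,
            apical = pop$f_v_apical, apex = pop$f_v_apical)
  unname(base[ring])
}

#' Simulate one patient's rest/stress study pair with known kinetics
#'
#' Draws patient-level rest flow and flow reserve, per-segment heterogeneity,
#' optional scar, and bolus characteristics; builds rest and stress dynamic
#' studies by forward simulation of the one-tissue model on a fine grid,
#' frame averaging, and Gaussian Poisson-surrogate noise. Ground truth is
#' attached to each study. Deterministic given `seed`.
#'
#' @param pop A [population_config()].
#' @param patient_id Label.
#' @param seed Integer seed for this patient.
#' @param scheme Segment scheme.
#' @return A `study_pair` whose studies carry `truth` tibbles.
#' @export
simulate_patient <- function(pop, patient_id = "patient", seed = 1L,
                             scheme = aha17_scheme()) {
  stopifnot(inherits(pop, "population_config"))
  validate_scheme(scheme)
  with_seed_(seed, {
    rest_mbf <- stats::rlnorm(1, log(pop$rest_mbf_median), pop$rest_mbf_sdlog)
    mfr <- stats::rlnorm(1, log(pop$mfr_median), pop$mfr_sdlog)
    seg_mult <- stats::rlnorm(17, 0, pop$segment_sdlog)
    scar <- stats::runif(1) < pop$scar_prevalence
    scar_mask <- seq_len(17) %in% pop$scar_segments & scar
    f_v <- clip(fv_base_by_segment(pop) + stats::rnorm(17, 0, pop$f_v_sd),
                0.02, 0.8)
    k2 <- stats::runif(17, pop$k2_range[1], pop$k2_range[2])
    bad <- stats::runif(1) < pop$bad_bolus_rate
    # a leaked/dispersed injection: broad, late first pass with a heavy
    # recirculation tail, so the peak/plateau QC ratio collapses
    peak_base <- if (bad) stats::runif(1, 60, 85) else
      clip(stats::rnorm(1, pop$peak_time_mean, pop$peak_time_sd), 12, 60)
    tail_base <- if (bad) stats::runif(1, 0.8, 1.4) else
      stats::rlnorm(1, log(pop$tail_fraction_median), pop$tail_fraction_sdlog)
    alpha_eff <- if (bad) 1 else pop$alpha_shape
    ext_amp <- stats::rlnorm(1, log(pop$extracardiac_amplitude_median),
                             pop$extracardiac_amplitude_sdlog)

    seg_flow_rest <- rest_mbf * seg_mult * ifelse(scar_mask, 1 - pop$scar_severity, 1)
    seg_flow_stress <- seg_flow_rest * mfr

    make_study <- function(condition, flows) {
      peak <- clip(peak_base + stats::rnorm(1, 0, 2), 12, 89)
      sched <- default_frame_schedule()
      aif <- gamma_variate_aif(sched, peak_time_s = peak,
                               alpha_shape = alpha_eff,
                               tail_fraction = tail_base,
                               background_level = pop$background_level,
                               dt_s = pop$dt_s)
      ext <- extracardiac_curve(sched, amplitude = ext_amp, dt_s = pop$dt_s)
      k1 <- uptake_from_flow(flows, pop$extraction)
      seg_tacs <- vapply(seq_len(17), function(i)
        simulate_true_tac(k1[i], k2[i], f_v[i], aif$fine, sched),
        numeric(nrow(sched)))
      colnames(seg_tacs) <- sprintf("seg%02d", 1:17)
      tacs <- tibble::as_tibble(seg_tacs)
      tacs$blood <- aif$values
      tacs$extracardiac <- ext$values
      if (pop$noise_scale > 0) {
        for (cl in names(tacs)) {
          v <- tacs[[cl]]
          sdv <- pop$noise_scale * sqrt(pmax(v, 1e-6) / sched$duration_s)
          tacs[[cl]] <- pmax(v + stats::rnorm(length(v), 0, sdv), 0)
        }
      }
      truth <- tibble::tibble(segment = sprintf("seg%02d", 1:17),
                              condition = condition, mbf = flows, k1 = k1,
                              k2 = k2, f_v = f_v, scar = scar_mask)
      dynamic_study(condition, sched, tacs, patient_id = patient_id,
                    truth = truth, blood_fine = aif$fine,
                    extracardiac_fine = ext$fine)
    }
    rest <- make_study("rest", seg_flow_rest)
    stress <- make_study("stress", seg_flow_stress)
    study_pair(rest, stress, patient_id = patient_id)
  })
}

#' Simulate a cohort of patients
#'
#' Per-patient seeds are derived from the master seed and the patient index
#' by stable hashing, so enlarging the cohort never reshuffles earlier
#' patients.
#'
#' @param pop A [population_config()].
#' @param seed Master seed (default `pop$seed`).
#' @param scheme Segment scheme.
#' @return Named list of `study_pair` objects (`pat001`, `pat002`, ...).
#' @export
simulate_population <- function(pop, seed = pop$seed, scheme = aha17_scheme()) {
  ids <- sprintf("pat%03d", seq_len(pop$n_patients))
  out <- purrr::map(seq_along(ids), function(i)
    simulate_patient(pop, patient_id = ids[i],
                     seed = derive_seed(seed, "patient", ids[i]),
                     scheme = scheme))
  stats::setNames(out, ids)
}

#' Ground-truth flow and reserve of a simulated pair
#'
#' @param pair A `study_pair` produced by [simulate_patient()].
#' @return Tibble with `segment`, `mbf_rest`, `mbf_stress`, `mfr`, `scar`.
#' @export
truth_of <- function(pair) {
  stopifnot(inherits(pair, "study_pair"))
  r <- pair$rest$truth; s <- pair$stress$truth
  if (is.null(r) || is.null(s)) abort_input("pair carries no ground truth")
  tibble::tibble(segment = r$segment, mbf_rest = r$mbf, mbf_stress = s$mbf,
                 mfr = s$mbf / r$mbf, scar = r$scar)
}
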