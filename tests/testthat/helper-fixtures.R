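# Shared fixture builders; everything is generated in code, no data files.

default_sched <- function() default_frame_schedule()

default_aif <- function(...) gamma_variate_aif(default_sched(), ...)

# A study whose 17 segments all carry the same supplied TAC (or a function
# of the segment index), with the default AIF as blood input.
uniform_study <- function(seg_values, condition = "rest", aif = default_aif(),
                          extracardiac = NULL) {
  sched <- aif$schedule
  tacs <- tibble::as_tibble(
    stats::setNames(
      lapply(1:17, function(i) {
        if (is.function(seg_values)) seg_values(i) else seg_values
      }),
      sprintf("seg%02d", 1:17)))
  tacs$blood <- aif$values
  if (!is.null(extracardiac)) tacs$extracardiac <- extracardiac
  dynamic_study(condition, sched, tacs, blood_fine = aif$fine)
}

# Small noiseless population for fast deterministic pipeline tests.
quiet_pop <- function(n = 6, ...) {
  population_config(n_patients = n, noise_scale = 0, bad_bolus_rate = 0,
                    scar_prevalence = 0, ...)
}

zero_perturbation <- function() {
  perturbation_config(valve_plane_sd = 0, axis_sd = 0, motion_sd = 0,
                      inferior_contamination_sd = 0)
}
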