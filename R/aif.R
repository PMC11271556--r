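#' Gamma-variate arterial input function for a rapid-bolus injection
#'
#' Models the left-ventricular blood-pool curve after a manual rapid bolus:
#' a gamma-variate first pass `(t/tp)^alpha * exp(alpha * (1 - t/tp))` peaking
#' at `peak_time_s`, a slow recirculation/clearance tail, and a constant
#' background from the small positioning pre-injection. The bolus-plus-tail
#' curve is normalised to unit peak on the fine grid before the background is
#' added; activity units are arbitrary throughout.
#'
#' @param schedule Frame-schedule tibble.
#' @param peak_time_s Time of the first-pass peak (seconds); must fall in the
#'   first 90 s of the acquisition.
#' @param alpha_shape Gamma-variate shape (> 0); larger is narrower.
#' @param tail_fraction Amplitude of the recirculation tail relative to the
#'   first-pass peak.
#' @param tail_decay_s Exponential decay time of the tail (seconds).
#' @param background_level Constant background as a fraction of the bolus
#'   peak; default 0.067 mirrors a 37 MBq positioning dose before a 550 MBq
#'   bolus.
#' @param dt_s Fine-grid step (seconds).
#' @return List with `values` (per-frame means), `fine` (tibble `time_s`,
#'   `value`) and the schedule.
#' @export
gamma_variate_aif <- function(schedule = default_frame_schedule(),
                              peak_time_s = 25, alpha_shape = 3,
                              tail_fraction = 0.08, tail_decay_s = 400,
                              background_level = 0.067, dt_s = 0.5) {
  validate_schedule(schedule)
  if (alpha_shape <= 0) abort_input("`alpha_shape` must be positive")
  assert_scalar_num(peak_time_s, "peak_time_s", lo = 1, hi = 90 + max(0, schedule$t_start_s[1]))
  assert_scalar_num(background_level, "background_level", lo = 0)
  assert_scalar_num(tail_fraction, "tail_fraction", lo = 0)
  tt <- fine_time_grid(schedule, dt_s)
  tp <- peak_time_s
  g <- ifelse(tt <= 0, 0, (tt / tp)^alpha_shape * exp(alpha_shape * (1 - tt / tp)))
  tail <- tail_fraction * (1 - exp(-pmax(tt, 0) / tp)) * exp(-pmax(tt, 0) / tail_decay_s)
  curve <- g + tail
  curve <- curve / max(curve)
  curve <- curve + background_level
  list(values = frame_average(tt, curve, schedule),
       fine = tibble::tibble(time_s = tt, value = curve),
       schedule = schedule)
}

#' Extracardiac (hepatic/intestinal) background curve
#'
#' A delayed, slowly rising curve of the kind seen in the liver and gut after
#' a sestamibi injection; this is the contamination source mixed into
#' inferior-wall segments by the operator-perturbation model.
#'
#' @param schedule Frame-schedule tibble.
#' @param amplitude Late plateau level relative to the blood-pool bolus peak.
#' @param rise_time_s Uptake time constant (seconds).
#' @param delay_s Appearance delay (seconds).
#' @param dt_s Fine-grid step (seconds).
#' @return List with `values` (per-frame means) and `fine`.
#' @export
extracardiac_curve <- function(schedule = default_frame_schedule(),
                               amplitude = 0.8, rise_time_s = 150,
                               delay_s = 20, dt_s = 0.5) {
  validate_schedule(schedule)
  assert_scalar_num(amplitude, "amplitude", lo = 0)
  tt <- fine_time_grid(schedule, dt_s)
  u <- pmax(tt - delay_s, 0) / rise_time_s
  curve <- amplitude * (1 - exp(-u))^2
  list(values = frame_average(tt, curve, schedule),
       fine = tibble::tibble(time_s = tt, value = curve),
       schedule = schedule)
}

#' Quality control of the blood-pool bolus
#'
#' Mirrors the visual bolus check used before quantification: the study fails
#' when the first-pass peak is not sharp (peak amplitude over late-plateau
#' amplitude below `min_peak_plateau_ratio`) or arrives too late (peak after
#' `latest_peak_frame`), as happens with a leaked or dispersed injection.
#' The late plateau is the mean of the last four (60-s) frames.
#'
#' @param blood_values Per-frame blood-pool TAC values.
#' @param min_peak_plateau_ratio Minimum acceptable peak/plateau ratio
#'   (default 3).
#' @param latest_peak_frame Latest acceptable peak frame index (default 15,
#'   the last 6-s frame).
#' @return One-row tibble: `pass`, `reason`, `peak_plateau_ratio`,
#'   `peak_frame`.
#' @export
bolus_qc <- function(blood_values, min_peak_plateau_ratio = 3,
                     latest_peak_frame = 15) {
  v <- as.numeric(blood_values)
  n <- length(v)
  if (n < 5 || all(v <= 0)) {
    return(tibble::tibble(pass = FALSE, reason = "degenerate blood curve",
                          peak_plateau_ratio = NA_real_, peak_frame = NA_integer_))
  }
  peak_frame <- which.max(v)
  plateau <- mean(v[max(1, n - 3):n])
  if (plateau <= 0) {
    return(tibble::tibble(pass = FALSE, reason = "zero late plateau",
                          peak_plateau_ratio = NA_real_, peak_frame = peak_frame))
  }
  ratio <- v[peak_frame] / plateau
  if (peak_frame > latest_peak_frame) {
    reason <- sprintf("late bolus peak (frame %d)", peak_frame)
    pass <- FALSE
  } else if (ratio < min_peak_plateau_ratio) {
    reason <- sprintf("flat bolus (peak/plateau %.2f)", ratio)
    pass <- FALSE
  } else {
    reason <- NA_character_
    pass <- TRUE
  }
  tibble::tibble(pass = pass, reason = reason,
                 peak_plateau_ratio = ratio, peak_frame = peak_frame)
}
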