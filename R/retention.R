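#' Configuration of the net retention model
#'
#' The net retention model estimates uptake as the late-window myocardial
#' concentration, corrected by a single global blood-pool spillover fraction
#' `beta` (the same for every segment), normalised by the integral of the
#' blood curve over the early bolus window:
#' `R_seg = (mean_late(C_seg) - beta * mean_late(C_b)) / int_0^T0 C_b dt`.
#'
#' Window defaults place the blood integral over the first 210 s (the 6-s and
#' 30-s frames, capturing the bolus first pass and early recirculation) and
#' the myocardial average over 210-450 s (the late frames, where sestamibi is
#' effectively trapped). Both windows must align with frame boundaries.
#'
#' @param beta Global blood spillover fraction in `[0, 1)`; default 0.15.
#' @param blood_window Two times (s), `c(0, T0)`, for the input integral.
#' @param myo_window Two times (s), `c(T1, T2)`, for the late myocardial mean.
#' @return An object of class `retention_config`.
#' @export
retention_config <- function(beta = 0.15, blood_window = c(0, 210),
                             myo_window = c(210, 450)) {
  assert_scalar_num(beta, "beta", lo = 0, hi = 1 - 1e-9)
  stopifnot(length(blood_window) == 2, length(myo_window) == 2)
  if (!(blood_window[1] < blood_window[2]) || !(myo_window[1] < myo_window[2]))
    abort_input("windows must be increasing intervals")
  if (blood_window[2] > myo_window[1] + 1e-9)
    abort_input("blood integral window must end before the myocardial window starts")
  structure(list(beta = beta, blood_window = blood_window,
                 myo_window = myo_window),
            class = "retention_config")
}

# Frames whose [start, end] lie inside the window; window edges must align
# with frame boundaries.
window_frames <- function(schedule, window, what) {
  sel <- schedule$t_start_s >= window[1] - 1e-9 & schedule$t_end_s <= window[2] + 1e-9
  if (!any(sel)) abort_input("%s window contains no frames", what)
  cover <- abs(min(schedule$t_start_s[sel]) - window[1]) < 1e-6 &&
    abs(max(schedule$t_end_s[sel]) - window[2]) < 1e-6
  if (!cover) abort_input("%s window [%g, %g] does not align with frame boundaries",
                          what, window[1], window[2])
  which(sel)
}

#' Net retention uptake per segment
#'
#' Applies the net retention formula (see [retention_config()]) to every
#' myocardial segment of a study. Means over the late window are
#' frame-duration weighted; the blood integral is the duration-weighted sum
#' of frame means over the early window (the exact integral of the
#' frame-averaged curve). The per-second rate is converted to per-minute
#' units once, at the end. A segment whose spillover-corrected numerator is
#' negative is clipped to zero uptake and flagged.
#'
#' @param study A `dynamic_study`.
#' @param cfg A [retention_config()].
#' @return Tibble with columns `segment`, `uptake` (1/min, equivalently
#'   ml/min/g in relative units) and `flagged`.
#' @export
ret_uptake <- function(study, cfg = retention_config()) {
  stopifnot(inherits(study, "dynamic_study"), inherits(cfg, "retention_config"))
  sched <- study$schedule
  fb <- window_frames(sched, cfg$blood_window, "blood integral")
  fm <- window_frames(sched, cfg$myo_window, "myocardial")
  dur_b <- sched$duration_s[fb]
  dur_m <- sched$duration_s[fm]
  blood <- study$tacs$blood
  blood_int <- sum(blood[fb] * dur_b)                # conc * s
  if (!is.finite(blood_int) || blood_int <= 0)
    abort_input("blood integral over [%g, %g] s must be positive",
                cfg$blood_window[1], cfg$blood_window[2])
  blood_late <- sum(blood[fm] * dur_m) / sum(dur_m)
  seg_cols <- grep("^seg", names(study$tacs), value = TRUE)
  num <- vapply(seg_cols, function(sg) {
    sum(study$tacs[[sg]][fm] * dur_m) / sum(dur_m) - cfg$beta * blood_late
  }, numeric(1))
  flagged <- num < 0
  uptake <- 60 * pmax(num, 0) / blood_int            # 1/s -> 1/min
  tibble::tibble(segment = seg_cols, uptake = unname(uptake),
                 flagged = unname(flagged))
}
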