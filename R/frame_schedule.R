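#' Build a dynamic frame schedule
#'
#' A frame schedule is a tibble with one row per reconstructed frame and
#' columns `frame`, `t_start_s`, `duration_s`, `t_mid_s`, `t_end_s`. Frames
#' are contiguous and non-overlapping: each frame starts where the previous
#' one ends.
#'
#' @param durations_s Numeric vector of strictly positive frame durations in
#'   seconds, in acquisition order.
#' @param t0_s Start time of the first frame (seconds, default 0).
#' @return A tibble with one row per frame.
#' @examples
#' frame_schedule(c(6, 6, 30))
#' @export
frame_schedule <- function(durations_s, t0_s = 0) {
  if (!is.numeric(durations_s) || length(durations_s) < 1 || any(!is.finite(durations_s)))
    abort_input("`durations_s` must be a non-empty finite numeric vector")
  if (any(durations_s <= 0))
    abort_input("frame durations must be strictly positive")
  starts <- t0_s + cumsum(c(0, durations_s[-length(durations_s)]))
  tibble::tibble(
    frame      = seq_along(durations_s),
    t_start_s  = starts,
    duration_s = as.numeric(durations_s),
    t_mid_s    = starts + durations_s / 2,
    t_end_s    = starts + durations_s
  )
}

#' The default 23-frame dynamic acquisition schedule
#'
#' Eight minutes of list-mode data reframed as fifteen 6-s frames, four 30-s
#' frames and four 60-s frames (23 frames, 450 s total), the binning used for
#' dynamic rest/stress myocardial perfusion SPECT on a CZT cardiac camera.
#'
#' @return A 23-row frame-schedule tibble (see [frame_schedule()]).
#' @export
default_frame_schedule <- function() {
  frame_schedule(c(rep(6, 15), rep(30, 4), rep(60, 4)))
}

validate_schedule <- function(schedule) {
  need <- c("frame", "t_start_s", "duration_s", "t_end_s")
  if (!is.data.frame(schedule) || !all(need %in% names(schedule)))
    abort_input("`schedule` must be a frame-schedule tibble (see frame_schedule())")
  if (any(schedule$duration_s <= 0))
    abort_input("frame durations must be strictly positive")
  gaps <- schedule$t_start_s[-1] - (schedule$t_start_s + schedule$duration_s)[-nrow(schedule)]
  if (any(abs(gaps) > 1e-9))
    abort_input("frames must be contiguous and non-overlapping")
  invisible(schedule)
}

#' Fine time grid spanning a frame schedule
#'
#' @param schedule Frame-schedule tibble.
#' @param dt_s Grid step in seconds (must divide every frame duration so that
#'   frame boundaries fall on grid points; default 0.5).
#' @return Numeric vector of times from the schedule start to its end.
#' @export
fine_time_grid <- function(schedule, dt_s = 0.5) {
  validate_schedule(schedule)
  assert_scalar_num(dt_s, "dt_s", lo = 1e-6, hi = 0.5)
  t0 <- schedule$t_start_s[1]
  t1 <- schedule$t_end_s[nrow(schedule)]
  n <- (t1 - t0) / dt_s
  if (abs(n - round(n)) > 1e-8)
    abort_input("`dt_s` must divide the schedule span exactly")
  seq(t0, t1, by = dt_s)
}

#' Average a finely sampled curve onto acquisition frames
#'
#' Computes, for each frame, the time average of a continuous-time curve over
#' `[t_start, t_end)` by trapezoidal integration on the supplied grid divided
#' by the frame duration. Frame boundaries not on the grid are inserted by
#' linear interpolation.
#'
#' @param fine_times Strictly increasing times (seconds) covering the full
#'   schedule, with step at most 0.5 s.
#' @param fine_values Curve values at `fine_times`.
#' @param schedule Frame-schedule tibble.
#' @return Numeric vector of per-frame means, one per schedule row.
#' @export
frame_average <- function(fine_times, fine_values, schedule) {
  validate_schedule(schedule)
  if (length(fine_times) != length(fine_values))
    abort_input("`fine_times` and `fine_values` must have equal length")
  if (length(fine_times) < 2 || any(diff(fine_times) <= 0))
    abort_input("`fine_times` must be strictly increasing with >= 2 points")
  if (max(diff(fine_times)) > 0.5 + 1e-9)
    abort_input("fine grid step must be <= 0.5 s")
  t0 <- schedule$t_start_s[1]; t1 <- schedule$t_end_s[nrow(schedule)]
  if (fine_times[1] > t0 + 1e-9 || fine_times[length(fine_times)] < t1 - 1e-9)
    abort_input("fine grid [%g, %g] does not cover the schedule [%g, %g]",
                fine_times[1], fine_times[length(fine_times)], t0, t1)
  bounds <- unique(c(schedule$t_start_s, schedule$t_end_s))
  tt <- sort(unique(c(fine_times, bounds)))
  tt <- tt[tt >= t0 - 1e-12 & tt <= t1 + 1e-12]
  vv <- stats::approx(fine_times, fine_values, xout = tt, rule = 2)$y
  # cumulative trapezoid, then per-frame increments
  ct <- c(0, cumsum(diff(tt) * (vv[-1] + vv[-length(vv)]) / 2))
  at <- function(x) stats::approx(tt, ct, xout = x, rule = 2)$y
  (at(schedule$t_end_s) - at(schedule$t_start_s)) / schedule$duration_s
}

# Frame-averaging operator as a dense matrix W (frames x grid points) with
# trapezoid weights, valid when every frame boundary lies on the grid.
# Hot-path companion of frame_average() for repeated model evaluations.
frame_average_matrix <- function(fine_times, schedule) {
  n <- length(fine_times)
  dt <- diff(fine_times)
  W <- matrix(0, nrow(schedule), n)
  for (f in seq_len(nrow(schedule))) {
    i0 <- which(abs(fine_times - schedule$t_start_s[f]) < 1e-9)
    i1 <- which(abs(fine_times - schedule$t_end_s[f]) < 1e-9)
    if (length(i0) != 1 || length(i1) != 1)
      abort_input("frame boundaries must lie on the fine grid")
    idx <- i0:i1
    w <- numeric(length(idx))
    seg <- dt[i0:(i1 - 1)]
    w[-length(w)] <- w[-length(w)] + seg / 2
    w[-1] <- w[-1] + seg / 2
    W[f, idx] <- w / schedule$duration_s[f]
  }
  W
}
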