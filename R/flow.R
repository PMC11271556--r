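#' Quantify myocardial blood flow for one study under one kinetic model
#'
#' Runs the chosen kinetic model on a study ([ret_uptake()] or [fit_1cm()]),
#' converts per-segment uptake to MBF through the extraction model, and
#' aggregates to vascular territories and the whole myocardium.
#'
#' @param study A `dynamic_study`.
#' @param model `"ret"` (net retention) or `"1cm"` (one-tissue compartment).
#' @param extraction An [extraction_model()].
#' @param ret_cfg A [retention_config()] (used when `model = "ret"`).
#' @param scheme Segment scheme, default [aha17_scheme()].
#' @param dt_s Fine-grid step for the compartment fit.
#' @return An object of class `flow_result` with tibbles `segments`
#'   (`segment`, `uptake`, `mbf`, `flagged`) and `territories` (`region`,
#'   `mbf`), plus the condition, model and diagnostics.
#' @export
compute_flow <- function(study, model = c("ret", "1cm"),
                         extraction = extraction_model(),
                         ret_cfg = retention_config(),
                         scheme = aha17_scheme(), dt_s = 0.5) {
  model <- match.arg(model)
  validate_scheme(scheme)
  fit <- NULL
  if (model == "ret") {
    up <- ret_uptake(study, ret_cfg)
  } else {
    fit <- fit_1cm(study, dt_s = dt_s)
    up <- fit$estimates |>
      dplyr::transmute(.data$segment, uptake = .data$k1,
                       flagged = !.data$converged)
  }
  conv <- flow_from_uptake(ifelse(is.finite(up$uptake), up$uptake, 0), extraction)
  segs <- tibble::tibble(segment = up$segment, uptake = up$uptake,
                         mbf = conv$mbf,
                         flagged = up$flagged | conv$saturated)
  terr <- aggregate_territories(
    tibble::tibble(segment = segs$segment, value = segs$mbf), scheme) |>
    dplyr::rename(mbf = "value")
  structure(list(segments = segs, territories = terr,
                 condition = study$condition, model = model,
                 patient_id = study$patient_id, fit = fit),
            class = "flow_result")
}

#' @export
print.flow_result <- function(x, ...) {
  cat(sprintf("<flow_result> %s, model %s\n", x$condition, toupper(x$model)))
  print(x$territories)
  invisible(x)
}

#' Myocardial flow reserve from stress and rest flow results
#'
#' Segment-wise MFR = stress MBF / rest MBF, computed before aggregation;
#' territory and TOT values are weight-averages of segment MFRs. Segments
#' with rest MBF below `min_rest_mbf` (near-scar flows where the ratio is
#' unstable) or flagged in either input are excluded from aggregation, with
#' weights renormalised.
#'
#' @param stress,rest `flow_result` objects for the same patient and model.
#' @param scheme Segment scheme.
#' @param min_rest_mbf Exclusion threshold on rest MBF (ml/min/g).
#' @return Object of class `mfr_result` with `segments` (`segment`, `mfr`,
#'   `flagged`) and `territories` (`region`, `mfr`).
#' @export
compute_mfr <- function(stress, rest, scheme = aha17_scheme(),
                        min_rest_mbf = 0.05) {
  stopifnot(inherits(stress, "flow_result"), inherits(rest, "flow_result"))
  if (stress$condition != "stress" || rest$condition != "rest")
    abort_input("`stress`/`rest` arguments have wrong condition tags")
  if (!identical(stress$segments$segment, rest$segments$segment))
    abort_input("stress and rest results use different segment sets")
  excl <- stress$segments$flagged | rest$segments$flagged |
    rest$segments$mbf < min_rest_mbf
  if (all(excl)) abort_input("all segments excluded; cannot form MFR")
  mfr <- ifelse(excl, NA_real_, stress$segments$mbf / rest$segments$mbf)
  segs <- tibble::tibble(segment = stress$segments$segment, mfr = mfr,
                         flagged = excl)
  terr <- aggregate_territories(
    tibble::tibble(segment = segs$segment, value = segs$mfr), scheme) |>
    dplyr::rename(mfr = "value")
  structure(list(segments = segs, territories = terr, model = stress$model,
                 patient_id = stress$patient_id),
            class = "mfr_result")
}

#' @export
print.mfr_result <- function(x, ...) {
  cat(sprintf("<mfr_result> model %s\n", toupper(x$model)))
  print(x$territories)
  invisible(x)
}
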