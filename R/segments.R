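#' The AHA 17-segment scheme with coronary territory assignment
#'
#' Standard division of the left ventricle into 17 segments grouped into the
#' three vascular territories: LAD (segments 1, 2, 7, 8, 13, 14, 17), LCx
#' (5, 6, 11, 12, 16) and RCA (3, 4, 9, 10, 15). Segment weights default to
#' uniform 1/17; the whole-myocardium aggregate (TOT) is the weighted mean
#' over all 17 segments.
#'
#' @param weights Optional numeric vector of 17 positive relative mass
#'   weights (normalised to sum to 1); default uniform.
#' @return A tibble with columns `segment` (`"seg01"`..`"seg17"`), `number`,
#'   `ring` (`basal`/`mid`/`apical`/`apex`), `territory` and `weight`.
#' @examples
#' aha17_scheme()
#' @export
aha17_scheme <- function(weights = NULL) {
  territory <- character(17)
  territory[c(1, 2, 7, 8, 13, 14, 17)] <- "LAD"
  territory[c(5, 6, 11, 12, 16)] <- "LCx"
  territory[c(3, 4, 9, 10, 15)] <- "RCA"
  ring <- c(rep("basal", 6), rep("mid", 6), rep("apical", 4), "apex")
  if (is.null(weights)) weights <- rep(1, 17)
  if (length(weights) != 17 || any(!is.finite(weights)) || any(weights <= 0))
    abort_input("`weights` must be 17 positive finite numbers")
  tibble::tibble(
    segment   = sprintf("seg%02d", 1:17),
    number    = 1:17,
    ring      = ring,
    territory = territory,
    weight    = weights / sum(weights)
  )
}

validate_scheme <- function(scheme) {
  need <- c("segment", "territory", "weight")
  if (!is.data.frame(scheme) || !all(need %in% names(scheme)) || nrow(scheme) != 17)
    abort_input("`scheme` must be a 17-row segment-scheme tibble (see aha17_scheme())")
  if (anyDuplicated(scheme$segment))
    abort_input("segment labels must be unique")
  if (!all(scheme$territory %in% c("LAD", "LCx", "RCA")))
    abort_input("territories must be LAD, LCx or RCA")
  if (abs(sum(scheme$weight) - 1) > 1e-9 || any(scheme$weight <= 0))
    abort_input("segment weights must be positive and sum to 1")
  invisible(scheme)
}

#' Aggregate per-segment values to vascular territories and the whole myocardium
#'
#' Weight-averages a per-segment quantity within each territory and over all
#' 17 segments (`TOT`). Segments whose value is `NA` (flagged/excluded) are
#' dropped and the remaining weights renormalised within each aggregate.
#'
#' @param data Data frame with columns `segment` and `value` (17 rows), or a
#'   named numeric vector of length 17.
#' @param scheme Segment-scheme tibble, default [aha17_scheme()].
#' @return A tibble with columns `region` (`LAD`, `LCx`, `RCA`, `TOT`),
#'   `value`, and `n_used` (segments contributing after exclusion).
#' @export
aggregate_territories <- function(data, scheme = aha17_scheme()) {
  validate_scheme(scheme)
  if (is.numeric(data)) {
    data <- tibble::tibble(segment = names(data) %||% scheme$segment, value = unname(data))
  }
  if (!all(c("segment", "value") %in% names(data)))
    abort_input("`data` must have columns `segment` and `value`")
  if (!setequal(data$segment, scheme$segment))
    abort_input("`data` must contain exactly the 17 scheme segments")
  d <- dplyr::left_join(scheme, data[c("segment", "value")], by = "segment")
  wmean <- function(v, w) {
    ok <- is.finite(v)
    if (!any(ok)) return(NA_real_)
    sum(v[ok] * w[ok]) / sum(w[ok])
  }
  terr <- d |>
    dplyr::group_by(region = .data$territory) |>
    dplyr::summarise(n_used = sum(is.finite(.data$value)),
                     value = wmean(.data$value, .data$weight),
                     .groups = "drop")
  tot <- tibble::tibble(region = "TOT",
                        value = wmean(d$value, d$weight),
                        n_used = sum(is.finite(d$value)))
  out <- dplyr::bind_rows(terr, tot)[c("region", "value", "n_used")]
  out[match(c("LAD", "LCx", "RCA", "TOT"), out$region), ]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
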