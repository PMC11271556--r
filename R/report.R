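#' Build a repeatability report from a grid of paired measurements
#'
#' Takes the long table of quantified values (one row per patient x
#' processing x model x parameter x region) and produces, for every
#' comparison x model x parameter x region cell, the full agreement summary
#' ([agreement_summary()]), plus per-cell cross-model tests mirroring a
#' models-side-by-side repeatability table: a paired Fisher-z comparison of
#' the two models' correlations, a paired t-test of their difference series,
#' and an F-test of the difference SDs.
#'
#' @param measurements Tibble with columns `patient_id`, `processing`,
#'   `model`, `parameter`, `region`, `value`.
#' @param comparisons Named list mapping comparison labels to the two
#'   processing labels compared; default inter-operator (first operator's
#'   first processing vs second operator) and intra-operator (first
#'   operator's two processings).
#' @return Object of class `repeatability_report` with tibbles `agreement`
#'   and `model_tests`.
#' @export
build_report <- function(measurements,
                         comparisons = list(
                           inter = c("op1_rep1", "op2"),
                           intra = c("op1_rep1", "op1_rep2"))) {
  need <- c("patient_id", "processing", "model", "parameter", "region", "value")
  if (!all(need %in% names(measurements)))
    abort_input("`measurements` must have columns %s", paste(need, collapse = ", "))
  models <- sort(unique(measurements$model))
  params <- unique(measurements$parameter)
  regions <- unique(measurements$region)

  paired_series <- function(cmp, mod, par, reg) {
    d <- measurements |>
      dplyr::filter(.data$model == mod, .data$parameter == par,
                    .data$region == reg,
                    .data$processing %in% comparisons[[cmp]]) |>
      dplyr::select("patient_id", "processing", "value") |>
      tidyr::pivot_wider(names_from = "processing", values_from = "value") |>
      tidyr::drop_na()
    if (!all(comparisons[[cmp]] %in% names(d)) || nrow(d) < 3)
      abort_input("report gap: no usable pairs for %s / %s / %s / %s",
                  cmp, mod, par, reg)
    list(a = d[[comparisons[[cmp]][1]]], b = d[[comparisons[[cmp]][2]]],
         ids = d$patient_id)
  }

  grid <- tidyr::expand_grid(comparison = names(comparisons), model = models,
                             parameter = params, region = regions)
  agreement <- purrr::pmap(grid, function(comparison, model, parameter, region) {
    s <- paired_series(comparison, model, parameter, region)
    dplyr::bind_cols(
      tibble::tibble(comparison = comparison, model = model,
                     parameter = parameter, region = region),
      agreement_summary(s$a, s$b))
  }) |> dplyr::bind_rows()

  model_tests <- NULL
  if (length(models) == 2) {
    tgrid <- tidyr::expand_grid(comparison = names(comparisons),
                                parameter = params, region = regions)
    model_tests <- purrr::pmap(tgrid, function(comparison, parameter, region) {
      s1 <- paired_series(comparison, models[1], parameter, region)
      s2 <- paired_series(comparison, models[2], parameter, region)
      ids <- intersect(s1$ids, s2$ids)
      i1 <- match(ids, s1$ids); i2 <- match(ids, s2$ids)
      a1 <- s1$a[i1]; b1 <- s1$b[i1]; a2 <- s2$a[i2]; b2 <- s2$b[i2]
      n <- length(ids)
      r1 <- suppressWarnings(spearman_r(a1, b1))
      r2 <- suppressWarnings(spearman_r(a2, b2))
      # inter-measure correlation for the dependent-correlation test:
      # rank correlation of the per-patient measurement means of both models
      r12 <- suppressWarnings(spearman_r((a1 + b1) / 2, (a2 + b2) / 2))
      rz <- if (any(!is.finite(c(r1, r2, r12))) || abs(r12) >= 1 ||
                abs(r1) >= 1 || abs(r2) >= 1)
        tibble::tibble(z = NA_real_, p = NA_real_)
      else tryCatch(fisher_z_dependent(r1, r2, r12, n),
                    mfrkit_input_error = function(e)
                      tibble::tibble(z = NA_real_, p = NA_real_))
      tt <- paired_t(a1 - b1, a2 - b2)
      d1 <- stats::sd(a1 - b1); d2 <- stats::sd(a2 - b2)
      ft <- if (d1 > 0 && d2 > 0) f_test_sd(d1, n, d2, n)
      else tibble::tibble(F = NA_real_, df1 = n - 1, df2 = n - 1, p = NA_real_)
      tibble::tibble(comparison = comparison, parameter = parameter,
                     region = region, n = n,
                     model_a = models[1], model_b = models[2],
                     r_a = r1, r_b = r2, r12 = r12,
                     z_r = rz$z, p_r = rz$p,
                     t_mean = tt$t, p_mean = tt$p,
                     F_sd = ft$F, p_sd = ft$p)
    }) |> dplyr::bind_rows()
  }
  structure(list(agreement = agreement, model_tests = model_tests,
                 comparisons = comparisons),
            class = "repeatability_report")
}

#' @export
print.repeatability_report <- function(x, ...) {
  cat(sprintf("<repeatability_report> %d agreement cells\n", nrow(x$agreement)))
  print(dplyr::select(x$agreement, "comparison", "model", "parameter",
                      "region", "r_spearman", "mean_diff", "sd_diff"))
  invisible(x)
}

fmt3 <- function(x) ifelse(is.finite(x), sprintf("%.3f", x), "NA")

md_table <- function(df) {
  cells <- vapply(df, function(col)
    if (is.numeric(col)) fmt3(col) else as.character(col),
    character(nrow(df)))
  if (is.null(dim(cells))) cells <- matrix(cells, nrow = 1)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, rows)
}

#' Render an experiment result or repeatability report to files
#'
#' Writes a machine-readable JSON twin and/or a markdown rendering with all
#' numerics at 3 decimals; re-rendering the same object produces identical
#' bytes.
#'
#' @param x An `experiment_result` or `repeatability_report`.
#' @param dir Output directory (created if needed).
#' @param format Subset of `c("json", "markdown")`.
#' @return Invisibly, the paths written.
#' @export
render_report <- function(x, dir, format = c("json", "markdown")) {
  format <- match.arg(format, several.ok = TRUE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  is_exp <- inherits(x, "experiment_result")
  rep_ <- if (is_exp) x$report else x
  stopifnot(inherits(rep_, "repeatability_report"))
  paths <- character(0)
  if ("json" %in% format) {
    p <- file.path(dir, "report.json")
    payload <- list(agreement = rep_$agreement, model_tests = rep_$model_tests)
    if (is_exp) payload <- c(payload, list(
      seed = x$seed, n_simulated = x$n_simulated,
      n_excluded = nrow(x$excluded), excluded = x$excluded,
      means = x$means))
    jsonlite::write_json(payload, p, dataframe = "rows", digits = NA,
                         auto_unbox = TRUE, na = "null", pretty = TRUE)
    paths <- c(paths, p)
  }
  if ("markdown" %in% format) {
    p <- file.path(dir, "report.md")
    lines <- c("# Repeatability report", "")
    if (is_exp) {
      lines <- c(lines,
                 sprintf("Seed: %d. Patients simulated: %d, excluded by bolus QC: %d, analysed: %d.",
                         x$seed, x$n_simulated, nrow(x$excluded),
                         x$n_simulated - nrow(x$excluded)), "")
      if (!is.null(x$means)) {
        lines <- c(lines, "## Mean values (first operator, first processing)", "",
                   md_table(dplyr::mutate(x$means, dplyr::across(
                     dplyr::where(is.numeric), ~ .x))), "")
      }
    }
    lines <- c(lines, "## Agreement (per comparison, model, parameter, region)", "",
               md_table(rep_$agreement), "")
    if (!is.null(rep_$model_tests))
      lines <- c(lines, "## Cross-model tests", "", md_table(rep_$model_tests), "")
    writeLines(lines, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
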